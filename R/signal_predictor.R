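#' Synthetic per-track signal store
#'
#' Holds per-chromosome, per-track non-negative signal as a step function
#' with a fixed step width (`step` bp): track `f` has the constant value
#' `signal[[chrom]][f, i]` on `[(i-1)*step, i*step)`. A step of 1 bp gives a
#' base-pair resolution array; coarser steps keep genome-scale synthetic
#' stores in memory. Means over arbitrary intervals are computed exactly
#' from cumulative integrals, so the averaging predictor built on top of the
#' store ([track_predictor()]) has a closed form.
#'
#' @param signal named list (one entry per chromosome) of `F x n_steps`
#'   numeric matrices, finite and non-negative.
#' @param step step width in bp.
#' @param chrom_lengths optional named chromosome lengths (bp); defaults to
#'   `n_steps * step` per chromosome.
#' @param seed optional seed recorded for provenance.
#' @return object of class `track_store`.
#' @export
track_store <- function(signal, step, chrom_lengths = NULL, seed = NULL) {
  stopifnot(is.list(signal), length(signal) > 0, !is.null(names(signal)))
  if (!is.numeric(step) || length(step) != 1 || step <= 0 ||
      step != floor(step))
    stop("step must be a positive integer (bp)")
  nt <- unique(vapply(signal, nrow, integer(1)))
  if (length(nt) != 1) stop("all chromosomes must have the same track count")
  for (ch in names(signal)) {
    v <- signal[[ch]]
    if (!is.matrix(v) || !is.numeric(v)) stop("signal[[", ch, "]] not a matrix")
    if (any(!is.finite(v))) stop("non-finite signal on ", ch)
    if (any(v < 0)) stop("negative signal on ", ch)
  }
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(signal, function(v) ncol(v) * step, numeric(1))
  stopifnot(all(names(signal) %in% names(chrom_lengths)))
  for (ch in names(signal))
    if (ncol(signal[[ch]]) * step < chrom_lengths[[ch]])
      stop("signal array on ", ch, " shorter than chromosome length")
  structure(list(step = as.integer(step), n_tracks = nt,
                 chrom_lengths = chrom_lengths[names(signal)],
                 signal = signal, seed = seed),
            class = "track_store")
}

#' @export
print.track_store <- function(x, ...) {
  cat("Synthetic track store:", x$n_tracks, "tracks,",
      length(x$signal), "chromosome(s), step", x$step, "bp\n")
  invisible(x)
}

#' Generate a random synthetic track store
#'
#' Draws smooth non-negative signal: uniform values at knots every
#' `knot_spacing` bp, linearly interpolated onto the step grid. Purely a
#' stand-in for the output of a trained epigenomic-signal model; it emulates
#' the smoothness scale of real chromatin tracks, nothing more.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_tracks number of tracks `F`.
#' @param step step width in bp of the stored arrays.
#' @param knot_spacing spacing of interpolation knots (bp).
#' @param seed RNG seed; the store is a pure function of its arguments.
#' @return a [track_store()].
#' @export
synth_track_store <- function(chrom_lengths, n_tracks = 20, step = 200,
                              knot_spacing = 2000, seed = 0) {
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)))
  sig <- with_seed(seed, {
    lapply(chrom_lengths, function(len) {
      n_steps <- as.integer(ceiling(len / step))
      knots <- seq(0, len + knot_spacing, by = knot_spacing)
      centers <- (seq_len(n_steps) - 0.5) * step
      v <- matrix(0, n_tracks, n_steps)
      for (f in seq_len(n_tracks)) {
        kv <- stats::runif(length(knots), 0, 2)
        v[f, ] <- stats::approx(knots, kv, xout = centers, rule = 2)$y
      }
      v
    })
  })
  names(sig) <- names(chrom_lengths)
  track_store(sig, step = step, chrom_lengths = chrom_lengths, seed = seed)
}

# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read a track store
#'
#' R-native RDS serialization (version 2) of a [track_store()];
#' `read_track_store(write_track_store(x))` reproduces `x` exactly.
#'
#' @param store a [track_store()].
#' @param path file path (conventionally `.rds`).
#' @return `path` invisibly (write); the store (read).
#' @export
write_track_store <- function(store, path) {
  stopifnot(inherits(store, "track_store"))
  saveRDS(store, path, version = 2)
  invisible(path)
}

#' @rdname write_track_store
#' @export
read_track_store <- function(path) {
  if (!file.exists(path)) stop("track store not found: ", path)
  store <- readRDS(path)
  if (!inherits(store, "track_store")) stop("not a track store: ", path)
  store
}

#' Construct a signal predictor
#'
#' The predictor contract: given a genomic interval whose length is a
#' positive multiple of the bin size (200 bp), return an `F x n_bins` matrix
#' of finite per-track signal, column `j` describing bin
#' `[start + 200(j-1), start + 200j)`, deterministically (identical queries
#' give identical output). Each bin is predicted from a 2000 bp context
#' window centred on it. Any signal model satisfying this contract — the
#' shipped synthetic averaging predictor, or an adapter around an external
#' trained network — can drive the feature pipeline.
#'
#' @param predict_fun `function(chrom, start, end)` returning the
#'   `F x n_bins` matrix.
#' @param n_tracks number of tracks `F` (2002 for the full-scale epigenomic
#'   track compendium; tests use small F).
#' @param chrom_lengths named chromosome lengths (bp).
#' @param bin_size predicted bin width, 200 bp.
#' @param context context window per predicted bin, 2000 bp.
#' @return object of class `signal_predictor`.
#' @export
signal_predictor <- function(predict_fun, n_tracks, chrom_lengths,
                             bin_size = 200L, context = 2000L) {
  stopifnot(is.function(predict_fun), n_tracks >= 1)
  structure(list(predict_fun = predict_fun, n_tracks = as.integer(n_tracks),
                 chrom_lengths = chrom_lengths,
                 bin_size = as.integer(bin_size),
                 context = as.integer(context)),
            class = "signal_predictor")
}

#' @export
print.signal_predictor <- function(x, ...) {
  cat("Signal predictor:", x$n_tracks, "tracks,", x$bin_size, "bp bins,",
      x$context, "bp context\n")
  invisible(x)
}

#' Predict per-bin signal over an interval
#'
#' Validates the contract around the predictor's own function: the interval
#' must be a positive multiple of the bin size on a known chromosome and
#' the result must be a finite `F x n_bins` matrix.
#'
#' @param p a [signal_predictor()].
#' @param chrom chromosome name.
#' @param start,end interval (0-based half-open); `end - start` must be a
#'   positive multiple of `p$bin_size` and lie within the chromosome.
#' @return `F x n_bins` matrix, `n_bins = (end - start) / bin_size`.
#' @export
predict_bins <- function(p, chrom, start, end) {
  stopifnot(inherits(p, "signal_predictor"))
  if (start >= end) stop("predict_bins: start must be < end")
  if (!chrom %in% names(p$chrom_lengths))
    stop("predict_bins: unknown chromosome ", chrom)
  if ((end - start) %% p$bin_size != 0)
    stop("predict_bins: interval length must be a multiple of ", p$bin_size)
  if (start < 0 || end > p$chrom_lengths[[chrom]])
    stop("predict_bins: interval outside chromosome ", chrom)
  n_bins <- (end - start) / p$bin_size
  m <- p$predict_fun(chrom, start, end)
  if (!is.matrix(m) || nrow(m) != p$n_tracks || ncol(m) != n_bins)
    stop("predictor returned wrong shape (expected ", p$n_tracks, " x ",
         n_bins, ")")
  if (any(!is.finite(m))) stop("predictor returned non-finite signal")
  m
}

#' Averaging predictor over a synthetic track store
#'
#' For each 200 bp bin, the predicted value of track `f` is the mean of the
#' store's signal for `f` over the bin's 2000 bp context window (centred on
#' the bin). Where the context extends past a chromosome end it is truncated
#' to the available bases — no padding value is invented. The mean over any
#' interval of the store's step function is computed exactly from cumulative
#' integrals, so predictions have a closed form suitable as a test oracle,
#' and the predictor is linear in the store.
#'
#' @param store a [track_store()].
#' @return a [signal_predictor()] with `F = store$n_tracks`.
#' @export
track_predictor <- function(store) {
  stopifnot(inherits(store, "track_store"))
  step <- store$step
  # cumulative integral per chromosome: cum[, i+1] = integral over [0, i*step)
  cums <- lapply(store$signal, function(v) {
    cbind(0, t(apply(v * step, 1, cumsum)))
  })
  # integral of the step function over [0, x), vectorized over positions x
  integral_at <- function(chrom, x) {
    v <- store$signal[[chrom]]
    cm <- cums[[chrom]]
    i <- pmin(floor(x / step), ncol(v))        # completed steps
    partial <- x - i * step
    idx <- pmin(i + 1L, ncol(v))               # step holding the remainder
    cm[, i + 1L, drop = FALSE] +
      v[, idx, drop = FALSE] * rep(partial, each = nrow(v))
  }
  half_ctx <- 1000L
  fun <- function(chrom, start, end) {
    n_bins <- (end - start) / 200L
    centers <- start + 200L * (seq_len(n_bins) - 1L) + 100L
    len <- store$chrom_lengths[[chrom]]
    a <- pmax(centers - half_ctx, 0)
    b <- pmin(centers + half_ctx, len)
    (integral_at(chrom, b) - integral_at(chrom, a)) /
      rep(b - a, each = store$n_tracks)
  }
  signal_predictor(fun, n_tracks = store$n_tracks,
                   chrom_lengths = store$chrom_lengths)
}
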