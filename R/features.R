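#' Build the 200-bin grid around a gene's TSS
#'
#' The linear feature scaffold covers 20,000 bp on each side of the TSS —
#' `[tss - 20000, tss + 20000)` — tiled by 200 bins of 200 bp
#' (100 on each side of the TSS); the window half-width is the linear
#' scope that spatial regions must fall outside of. Bins are ordered 5' to
#' 3' relative to the
#' gene's strand: index 1 is always the most upstream bin, so for a
#' minus-strand gene the genomic order is reversed. Bins extending past the
#' chromosome start (or a known chromosome end) are flagged missing and
#' contribute zero signal.
#'
#' @param gene one-row slice of a gene table (`gene_id, chrom, tss, strand`).
#' @param chrom_length optional chromosome length to flag right-truncation.
#' @param window total window width in bp (default 40000: 20 kb per side).
#' @param bin_size bin width in bp (default 200).
#' @return object of class `bin_grid` with elements `chrom`, `tss`,
#'   `strand`, `bins` (data.frame `start, end, side, missing` in strand
#'   order), `genomic_order` (index mapping strand order -> genomic order)
#'   and `truncated` flag.
#' @export
build_bin_grid <- function(gene, chrom_length = NULL, window = 40000L,
                           bin_size = 200L) {
  stopifnot(window %% (2L * bin_size) == 0)
  tss <- as.integer(gene$tss)
  half <- window %/% 2L
  n_bins <- window %/% bin_size
  starts <- tss - half + bin_size * (seq_len(n_bins) - 1L)  # genomic order
  ends <- starts + bin_size
  missing <- starts < 0L
  if (!is.null(chrom_length)) missing <- missing | ends > chrom_length
  side <- ifelse(starts < tss, "left", "right")  # genomic left/right of TSS
  strand <- as.character(gene$strand)
  if (strand == "+") {
    ord <- seq_len(n_bins)
    upstream <- side == "left"
  } else {
    ord <- rev(seq_len(n_bins))
    upstream <- side == "right"
  }
  bins <- data.frame(start = starts, end = ends,
                     side = ifelse(upstream, "upstream", "downstream"),
                     missing = missing, stringsAsFactors = FALSE)[ord, ]
  rownames(bins) <- NULL
  if (any(missing))
    message("bin grid for ", gene$gene_id, ": ", sum(missing),
            " bin(s) outside the chromosome, recorded as missing")
  structure(list(gene_id = as.character(gene$gene_id), chrom = gene$chrom,
                 tss = tss, strand = strand, window = as.integer(window),
                 bin_size = as.integer(bin_size), bins = bins,
                 genomic_order = ord, truncated = any(missing)),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("Bin grid for", x$gene_id, ":", nrow(x$bins), "bins of", x$bin_size,
      "bp on", x$chrom, "around TSS", x$tss, paste0("(", x$strand, ")"),
      if (x$truncated) "[truncated]" else "", "\n")
  invisible(x)
}

#' Per-track signal over a gene's bin grid
#'
#' Runs the signal predictor over the grid's window and returns the
#' `F x 200` matrix with columns in the grid's strand order. Missing
#' (off-chromosome) bins are zero.
#'
#' @param grid a [build_bin_grid()] result.
#' @param predictor a [signal_predictor()].
#' @return `F x n_bins` numeric matrix, columns in strand order.
#' @export
window_signal <- function(grid, predictor) {
  stopifnot(inherits(grid, "bin_grid"), inherits(predictor, "signal_predictor"))
  n_bins <- nrow(grid$bins)
  out <- matrix(0, predictor$n_tracks, n_bins)
  # back to genomic order to find the contiguous in-chromosome run
  genomic <- grid$bins[order(grid$genomic_order), ]
  ok <- !genomic$missing
  if (any(ok)) {
    s <- min(genomic$start[ok])
    e <- max(genomic$end[ok])
    m <- predict_bins(predictor, grid$chrom, s, e)
    cols_genomic <- which(genomic$start >= s & genomic$start < e)
    full <- matrix(0, predictor$n_tracks, n_bins)
    full[, cols_genomic] <- m
    out <- full[, grid$genomic_order, drop = FALSE]
  }
  out
}

#' Exponential decay basis over the TSS window
#'
#' Positional weighting of the 200-bin window: `K` exponential decay scales
#' per side of the TSS. Row `k` (k = 1..K) weights upstream bins by
#' `exp(-d / lambda[k])` where `d` is the distance in bp from the bin
#' center to the TSS, and is zero on downstream bins; row `K + k` is the
#' mirror image for the downstream side. With `F` tracks this turns the
#' `F x 200` window signal into `F x 2K` decay features (40,040 at the
#' full-scale `F = 2002`, `K = 10`).
#'
#' Decay lengths default to a geometric ladder `lambda_k = 200 * 2^(k-1)` bp
#' (one bin width up to ~half the window and beyond), spanning the scales of
#' the window; they are a stated configuration choice.
#'
#' @param K decay scales per side (default 10).
#' @param lambdas vector of `K` positive decay lengths (bp).
#' @param window,bin_size window geometry, must match the bin grid.
#' @return object of class `decay_basis` with the `2K x 200` weight matrix
#'   `W` laid out for strand-ordered bins (upstream rows first).
#' @export
decay_basis <- function(K = 10L, lambdas = 200 * 2^(seq_len(K) - 1),
                        window = 40000L, bin_size = 200L) {
  stopifnot(K >= 1, length(lambdas) == K, all(lambdas > 0))
  n_bins <- window %/% bin_size
  half <- n_bins %/% 2L
  # strand-ordered distances of bin centers to the TSS:
  # bin 1 = most upstream (d = window/2 - bin/2), bin half = adjacent upstream
  d_up <- rev(bin_size * (seq_len(half) - 1L) + bin_size / 2)
  d_down <- bin_size * (seq_len(half) - 1L) + bin_size / 2
  W <- matrix(0, 2L * K, n_bins)
  for (k in seq_len(K)) {
    W[k, seq_len(half)] <- exp(-d_up / lambdas[k])
    W[K + k, half + seq_len(half)] <- exp(-d_down / lambdas[k])
  }
  structure(list(K = as.integer(K), lambdas = lambdas, W = W,
                 window = as.integer(window), bin_size = as.integer(bin_size)),
            class = "decay_basis")
}

#' @export
print.decay_basis <- function(x, ...) {
  cat("Decay basis:", x$K, "scales per side, lambdas",
      paste(signif(x$lambdas, 3), collapse = ", "), "bp\n")
  invisible(x)
}

#' Decay-weighted linear features
#'
#' Contracts the strand-ordered `F x 200` window signal against the decay
#' basis: `out[f, k] = sum_j W[k, j] * signal[f, j]`, giving `F x 2K`
#' features per gene.
#'
#' @param signal `F x 200` matrix from [window_signal()] (strand order).
#' @param basis a [decay_basis()].
#' @return `F x 2K` numeric matrix.
#' @export
linear_features <- function(signal, basis) {
  stopifnot(inherits(basis, "decay_basis"))
  if (!is.matrix(signal) || ncol(signal) != ncol(basis$W))
    stop("signal must be an F x ", ncol(basis$W), " matrix")
  signal %*% t(basis$W)
}

#' Select spatially close distal regions for a gene
#'
#' Implements the contact-based region selection: among all contacts with
#' one anchor overlapping the TSS anchor window — `[tss, tss + resolution)`,
#' i.e. one contact-matrix bin starting at the TSS — keep those observed at
#' least `min_count` times, and whose other anchor falls entirely outside
#' the linear scope `[tss - linear_scope, tss + linear_scope)` already
#' covered by the decay features. The surviving other-anchors are the
#' spatially close regions; they are de-duplicated (a region qualifying via
#' several contacts counts once) and sorted. If none survive, the selection
#' is flagged for the linear fallback.
#'
#' @param cs a [contact_set()].
#' @param gene one-row gene-table slice.
#' @param linear_scope half-width in bp of the linearly covered scope
#'   (default 20000).
#' @param min_count minimum contact count (default 2).
#' @param anchor_mode `"point"`: anchor window is `[tss, tss + resolution)`
#'   (the literal reading); `"bin"`: the contact-matrix bin containing the
#'   TSS.
#' @return object of class `spatial_selection`: `regions` (data.frame
#'   `chrom, start, end`), `used_fallback`, `gene_id`.
#' @export
select_spatial_regions <- function(cs, gene, linear_scope = 20000L,
                                   min_count = 2L,
                                   anchor_mode = c("point", "bin")) {
  stopifnot(inherits(cs, "contact_set"))
  anchor_mode <- match.arg(anchor_mode)
  tss <- as.integer(gene$tss)
  res <- cs$resolution
  if (anchor_mode == "point") {
    win <- c(tss, tss + res)
  } else {
    b0 <- (tss %/% res) * res
    win <- c(b0, b0 + res)
  }
  hits <- query_anchored(cs, gene$chrom, win[1], win[2])
  scope_lo <- tss - linear_scope
  scope_hi <- tss + linear_scope
  regions <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  if (nrow(hits) > 0) {
    hits <- hits[hits$count >= min_count, , drop = FALSE]
    pick <- function(s, e) s >= scope_hi | e <= scope_lo  # entirely outside
    ov1 <- hits$start1 < win[2] & hits$end1 > win[1]
    ov2 <- hits$start2 < win[2] & hits$end2 > win[1]
    keep1 <- ov1 & pick(hits$start2, hits$end2)  # partner of anchor1
    keep2 <- ov2 & pick(hits$start1, hits$end1)
    regions <- rbind(
      data.frame(chrom = hits$chrom[keep1], start = hits$start2[keep1],
                 end = hits$end2[keep1], stringsAsFactors = FALSE),
      data.frame(chrom = hits$chrom[keep2], start = hits$start1[keep2],
                 end = hits$end1[keep2], stringsAsFactors = FALSE))
    regions <- unique(regions)
    regions <- regions[order(regions$start), , drop = FALSE]
    rownames(regions) <- NULL
  }
  structure(list(gene_id = as.character(gene$gene_id), regions = regions,
                 used_fallback = nrow(regions) == 0,
                 resolution = res, linear_scope = as.integer(linear_scope),
                 min_count = as.integer(min_count)),
            class = "spatial_selection")
}

#' @export
print.spatial_selection <- function(x, ...) {
  if (x$used_fallback)
    cat("Spatial selection for", x$gene_id, ": no qualifying contacts",
        "(linear fallback)\n")
  else
    cat("Spatial selection for", x$gene_id, ":", nrow(x$regions),
        "distal region(s)\n")
  invisible(x)
}

#' Spatial feature vector for a gene
#'
#' Sums the predicted per-track signal over every 200 bp bin of every
#' selected distal region, yielding one value per track — a single extra
#' feature column that keeps the tensor uniform in size regardless of how
#' many regions a gene contacts. When the selection is empty (fallback),
#' the gene's own window signal is summed instead, deliberately without the
#' exponential decay transform, to stay on the same scale as the spatial
#' branch.
#'
#' Regions whose width is not a multiple of 200 bp are truncated to the
#' largest contained multiple before prediction; regions extending past the
#' chromosome are clipped likewise.
#'
#' @param sel a [select_spatial_regions()] result.
#' @param predictor a [signal_predictor()].
#' @param grid the gene's [build_bin_grid()] (needed for the fallback).
#' @param signal optional precomputed [window_signal()] matrix; computed on
#'   demand when the fallback requires it.
#' @return numeric vector of length `F`.
#' @export
spatial_feature <- function(sel, predictor, grid, signal = NULL) {
  stopifnot(inherits(sel, "spatial_selection"),
            inherits(predictor, "signal_predictor"))
  if (sel$used_fallback) {
    if (is.null(signal)) signal <- window_signal(grid, predictor)
    return(rowSums(signal))
  }
  acc <- numeric(predictor$n_tracks)
  for (i in seq_len(nrow(sel$regions))) {
    r <- sel$regions[i, ]
    s <- max(0L, r$start)
    e <- min(predictor$chrom_lengths[[r$chrom]], r$end)
    len <- ((e - s) %/% 200L) * 200L
    if (len <= 0) {
      message("spatial_feature: region ", r$chrom, ":", r$start, "-", r$end,
              " too short after snapping to 200 bp; skipped")
      next
    }
    m <- tryCatch(predict_bins(predictor, r$chrom, s, s + len),
                  error = function(e2)
                    stop("predictor failed on region ", r$chrom, ":",
                         r$start, "-", r$end, ": ", conditionMessage(e2)))
    acc <- acc + rowSums(m)
  }
  acc
}

#' Assemble a gene's feature tensor
#'
#' Binds the `F x 2K` decay features and the length-`F` spatial feature into
#' the per-gene `F x (2K + 1)` tensor, the spatial column last (at the
#' full-scale `F = 2002`, `K = 10` this is the 2002 x 21 tensor). The
#' flattening order used downstream is track-major: each track's `2K + 1`
#' values are contiguous.
#'
#' @param lin `F x 2K` matrix from [linear_features()].
#' @param sp length-`F` vector from [spatial_feature()].
#' @param gene_id gene identifier.
#' @param K decay scales per side.
#' @param resolution contact resolution the spatial column was built at.
#' @param fallback logical: was the linear fallback used.
#' @return object of class `feature_tensor`.
#' @export
assemble_tensor <- function(lin, sp, gene_id, K, resolution, fallback) {
  if (!is.matrix(lin) || nrow(lin) != length(sp))
    stop("row mismatch: linear features have ", nrow(lin),
         " tracks, spatial vector ", length(sp))
  if (ncol(lin) != 2L * K)
    stop("linear features must have 2K = ", 2L * K, " columns")
  m <- cbind(lin, sp)
  dimnames(m) <- NULL
  if (any(!is.finite(m))) stop("non-finite tensor entry for ", gene_id)
  structure(list(gene_id = as.character(gene_id), matrix = m,
                 K = as.integer(K), n_tracks = nrow(m),
                 resolution = as.integer(resolution),
                 fallback = isTRUE(fallback)),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat("Feature tensor for", x$gene_id, ":", x$n_tracks, "tracks x",
      ncol(x$matrix), "columns (2K =", 2 * x$K, "decay + 1 spatial)",
      if (x$fallback) "[fallback]" else "", "\n")
  invisible(x)
}

#' Flatten / unflatten a feature tensor
#'
#' Track-major flattening: track 1's `2K + 1` values first, then track 2's,
#' and so on; names are `t<track>.d<k>` for decay features and `t<track>.sp`
#' for the spatial column. The layout is recorded in the tensor archive so a
#' model can refuse mismatched feature matrices.
#'
#' @param tensor a [assemble_tensor()] result.
#' @return named numeric vector of length `F * (2K + 1)`.
#' @export
flatten_tensor <- function(tensor) {
  stopifnot(inherits(tensor, "feature_tensor"))
  v <- as.vector(t(tensor$matrix))
  names(v) <- tensor_feature_names(tensor$n_tracks, tensor$K)
  v
}

tensor_feature_names <- function(n_tracks, K) {
  cols <- c(paste0("d", seq_len(2L * K)), "sp")
  as.vector(t(outer(paste0("t", seq_len(n_tracks)), cols, paste, sep = ".")))
}

#' @rdname flatten_tensor
#' @param v flattened vector.
#' @param n_tracks,K tensor geometry.
#' @return for `unflatten_tensor`, the `F x (2K + 1)` matrix.
#' @export
unflatten_tensor <- function(v, n_tracks, K) {
  stopifnot(length(v) == n_tracks * (2L * K + 1L))
  matrix(v, nrow = n_tracks, ncol = 2L * K + 1L, byrow = TRUE)
}

#' Build the feature tensor for one gene
#'
#' Convenience wrapper running the whole per-gene pipeline: bin grid ->
#' window signal -> decay features; contact selection -> spatial feature;
#' assembly.
#'
#' @param gene one-row gene-table slice.
#' @param cs a [contact_set()].
#' @param predictor a [signal_predictor()].
#' @param basis a [decay_basis()].
#' @param linear_scope,min_count,anchor_mode see [select_spatial_regions()].
#' @return a [assemble_tensor()] result.
#' @export
build_gene_tensor <- function(gene, cs, predictor, basis,
                              linear_scope = 20000L, min_count = 2L,
                              anchor_mode = "point") {
  grid <- build_bin_grid(gene,
                         chrom_length = predictor$chrom_lengths[[gene$chrom]],
                         window = basis$window, bin_size = basis$bin_size)
  sig <- window_signal(grid, predictor)
  lin <- linear_features(sig, basis)
  sel <- select_spatial_regions(cs, gene, linear_scope = linear_scope,
                                min_count = min_count,
                                anchor_mode = anchor_mode)
  sp <- spatial_feature(sel, predictor, grid, signal = sig)
  assemble_tensor(lin, sp, gene$gene_id, K = basis$K,
                  resolution = cs$resolution, fallback = sel$used_fallback)
}
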