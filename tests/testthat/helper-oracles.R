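# Independent brute-force / textbook oracles used against the implementation.

# linear scan over every contact row: anchor overlap with [a, b), half-open
oracle_query <- function(contacts, chrom, a, b) {
  hit <- logical(nrow(contacts))
  for (i in seq_len(nrow(contacts))) {
    r <- contacts[i, ]
    if (r$chrom != chrom) next
    ov1 <- r$start1 < b && r$end1 > a
    ov2 <- r$start2 < b && r$end2 > a
    hit[i] <- ov1 || ov2
  }
  contacts[hit, , drop = FALSE]
}

# exhaustive filter implementing the spatial-region rule row by row
oracle_select <- function(contacts, resolution, tss, linear_scope = 20000,
                          min_count = 2) {
  win_lo <- tss
  win_hi <- tss + resolution
  scope_lo <- tss - linear_scope
  scope_hi <- tss + linear_scope
  out <- NULL
  for (i in seq_len(nrow(contacts))) {
    r <- contacts[i, ]
    if (r$count < min_count) next
    anchors <- list(c(r$start1, r$end1), c(r$start2, r$end2))
    for (j in 1:2) {
      a <- anchors[[j]]
      o <- anchors[[3 - j]]
      overlaps_win <- a[1] < win_hi && a[2] > win_lo
      outside_scope <- o[1] >= scope_hi || o[2] <= scope_lo
      if (overlaps_win && outside_scope)
        out <- rbind(out, data.frame(start = o[1], end = o[2]))
    }
  }
  if (is.null(out)) return(data.frame(start = integer(0), end = integer(0)))
  out <- unique(out)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# double-loop decay contraction
oracle_linear_features <- function(signal, W) {
  out <- matrix(0, nrow(signal), nrow(W))
  for (f in seq_len(nrow(signal)))
    for (k in seq_len(nrow(W)))
      for (j in seq_len(ncol(signal)))
        out[f, k] <- out[f, k] + W[k, j] * signal[f, j]
  out
}

# textbook Welch statistic with Satterthwaite degrees of freedom
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# random intra-chromosomal binned contact table
random_contacts <- function(n, resolution, chroms = c("chr1", "chr2"),
                            max_bin = 200) {
  b1 <- sample.int(max_bin, n, replace = TRUE) - 1L
  b2 <- sample.int(max_bin, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start1 = b1 * resolution, end1 = (b1 + 1L) * resolution,
             start2 = b2 * resolution, end2 = (b2 + 1L) * resolution,
             count = sample.int(5L, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# constant-signal track store: every track has value `value` everywhere
constant_store <- function(value, n_tracks, chrom_lengths, step = 200) {
  sig <- lapply(chrom_lengths, function(len)
    matrix(value, n_tracks, ceiling(len / step)))
  names(sig) <- names(chrom_lengths)
  track_store(sig, step = step, chrom_lengths = chrom_lengths)
}

# small synthetic dataset shared across tests (memoized)
.fixture_cache <- new.env(parent = emptyenv())
cached_dataset <- function(key, cfg) {
  if (is.null(.fixture_cache[[key]])) {
    ds <- synth_generate(cfg)
    predictor <- track_predictor(ds$store)
    archive <- suppressMessages(build_tensor_archive(
      ds$genes, ds$contact_set, predictor, decay_basis(K = cfg$K),
      verbose = FALSE))
    .fixture_cache[[key]] <- list(ds = ds, predictor = predictor,
                                  archive = archive)
  }
  .fixture_cache[[key]]
}

small_dataset <- function() {
  cached_dataset("small", synth_config(n_genes = 80, seed = 42))
}
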