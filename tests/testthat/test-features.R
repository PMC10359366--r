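gene_row <- function(id = "G1", chrom = "chr1", tss = 100000, strand = "+") {
  data.frame(gene_id = id, chrom = chrom, tss = tss, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("bin grid tiles the +/-20 kb window and follows strand orientation", {
  g <- build_bin_grid(gene_row(tss = 100000, strand = "+"))
  expect_equal(nrow(g$bins), 200L)
  expect_equal(g$bins$start[1], 80000L)          # most upstream bin
  expect_equal(g$bins$end[200], 120000L)
  expect_true(all(diff(g$bins$start) == 200L))   # gapless tiling
  expect_equal(sum(g$bins$side == "upstream"), 100L)
  expect_equal(g$bins$start[101], 100000L)       # bin 101 starts at the TSS

  gm <- build_bin_grid(gene_row(strand = "-"))
  # same genomic bins, reversed order: index 1 is the most upstream bin,
  # which for a minus-strand gene lies at coordinates above the TSS
  expect_equal(sort(gm$bins$start), sort(g$bins$start))
  expect_equal(gm$bins$start[1], 119800L)
  expect_true(all(gm$bins$start[gm$bins$side == "upstream"] >= 100000L))
})

test_that("a window running off the chromosome start is flagged, not fatal", {
  expect_message(g <- build_bin_grid(gene_row(tss = 5000)), "missing")
  expect_true(g$truncated)
  expect_equal(sum(g$bins$missing), 75L)  # bins below coordinate 0
  store <- constant_store(2, 3, c(chr1 = 1e5))
  sig <- window_signal(g, track_predictor(store))
  expect_equal(dim(sig), c(3L, 200L))
  expect_true(all(sig[, g$bins$missing] == 0))   # missing bins: zero signal
  expect_true(all(sig[, !g$bins$missing] > 0))
})

test_that("decay basis weights obey side masks, range and monotone decay", {
  b <- decay_basis(K = 10)
  expect_equal(dim(b$W), c(20L, 200L))
  expect_true(all(b$W >= 0 & b$W <= 1))
  expect_true(all(b$W[1:10, 101:200] == 0))   # upstream rows, downstream bins
  expect_true(all(b$W[11:20, 1:100] == 0))
  # within the active side, weight decreases with distance from the TSS
  for (k in c(1, 5, 10)) {
    expect_true(all(diff(b$W[k, 1:100]) > 0))       # toward the TSS
    expect_true(all(diff(b$W[10 + k, 101:200]) < 0))
  }
  # lambda -> infinity limit: each feature is the plain sum of its side
  binf <- decay_basis(K = 2, lambdas = c(1e12, 1e12))
  sig <- matrix(runif(3 * 200), 3, 200)
  lf <- linear_features(sig, binf)
  expect_equal(lf[, 1], rowSums(sig[, 1:100]), tolerance = 1e-7)
  expect_equal(lf[, 4], rowSums(sig[, 101:200]), tolerance = 1e-7)
})

test_that("decay contraction matches the brute-force double loop", {
  set.seed(21)
  sig <- matrix(rnorm(3 * 200), 3, 200)
  b <- decay_basis(K = 2, lambdas = c(400, 3200))
  expect_equal(linear_features(sig, b), oracle_linear_features(sig, b$W))
  expect_error(linear_features(sig[, 1:50], b), "F x 200")
})

test_that("spatial region selection applies the anchor, count and scope rules", {
  g <- gene_row(tss = 100000)
  mk_cs <- function(...) contact_set(data.frame(...), 5000)
  # qualifying: anchored at [100000,105000), partner at 400 kb, count 3
  cs <- mk_cs(chrom = "chr1", start1 = 100000, end1 = 105000,
              start2 = 400000, end2 = 405000, count = 3)
  sel <- select_spatial_regions(cs, g)
  expect_false(sel$used_fallback)
  expect_equal(sel$regions$start, 400000)
  # same contact seen once: below the count threshold
  cs1 <- mk_cs(chrom = "chr1", start1 = 100000, end1 = 105000,
               start2 = 400000, end2 = 405000, count = 1)
  expect_true(select_spatial_regions(cs1, g)$used_fallback)
  # partner inside the 20 kb linear scope: excluded despite count 5
  cs2 <- mk_cs(chrom = "chr1", start1 = 100000, end1 = 105000,
               start2 = 110000, end2 = 115000, count = 5)
  expect_true(select_spatial_regions(cs2, g)$used_fallback)
  # two contacts to the same distal bin: deduplicated to one region
  cs3 <- contact_set(data.frame(chrom = "chr1",
                                start1 = c(100000, 400000),
                                end1 = c(105000, 405000),
                                start2 = c(400000, 100000),
                                end2 = c(405000, 105000),
                                count = c(2, 4)), 5000)
  expect_equal(nrow(select_spatial_regions(cs3, g)$regions), 1L)
})

test_that("region selection equals the exhaustive filter on random sets", {
  for (seed in 1:3) {
    set.seed(seed)
    contacts <- random_contacts(2000, resolution = 5000, chroms = "chr1",
                                max_bin = 300)
    cs <- contact_set(contacts, 5000)
    for (tss in sample(seq(30000, 1400000, by = 1000), 10)) {
      g <- gene_row(tss = tss)
      sel <- select_spatial_regions(cs, g)
      want <- oracle_select(cs$contacts, 5000, tss)
      expect_equal(sel$regions[, c("start", "end")], want)
      expect_equal(sel$used_fallback, nrow(want) == 0)
      # monotonicity: min_count 1 never removes, larger scope never adds
      sel1 <- select_spatial_regions(cs, g, min_count = 1)
      expect_true(all(sel$regions$start %in% sel1$regions$start))
      sel_wide <- select_spatial_regions(cs, g, linear_scope = 50000)
      expect_true(all(sel_wide$regions$start %in% sel$regions$start))
    }
  }
})

test_that("spatial feature sums region signal, with the no-decay fallback", {
  lens <- c(chr1 = 1e6)
  store <- constant_store(3, n_tracks = 4, lens)
  p <- track_predictor(store)
  g <- gene_row(tss = 100000)
  grid <- build_bin_grid(g, chrom_length = lens[["chr1"]])
  # one region of 2 bins of 200 bp at constant signal c = 3 -> 2c per track
  sel <- select_spatial_regions(
    contact_set(data.frame(chrom = "chr1", start1 = 100000, end1 = 100400,
                           start2 = 400000, end2 = 400400, count = 2), 400), g)
  expect_equal(spatial_feature(sel, p, grid), rep(6, 4))
  # empty selection: fallback = unweighted column sum of the window signal
  sel_empty <- select_spatial_regions(
    contact_set(data.frame(chrom = "chr1", start1 = 0, end1 = 400,
                           start2 = 800, end2 = 1200, count = 1)[0, ], 400), g)
  expect_true(sel_empty$used_fallback)
  sig <- window_signal(grid, p)
  expect_equal(spatial_feature(sel_empty, p, grid), rowSums(sig))
  expect_equal(spatial_feature(sel_empty, p, grid), rep(3 * 200, 4))
})

test_that("tensors assemble, flatten and round-trip through the archive", {
  set.seed(5)
  lin <- matrix(rnorm(4 * 20), 4, 20)
  sp <- rnorm(4)
  t1 <- assemble_tensor(lin, sp, "G1", K = 10, resolution = 5000,
                        fallback = FALSE)
  expect_equal(dim(t1$matrix), c(4L, 21L))
  expect_equal(t1$matrix[, 21], sp)
  expect_equal(t1$matrix[, 1:20], lin)
  v <- flatten_tensor(t1)
  expect_equal(length(v), 4 * 21)
  expect_equal(names(v)[21:22], c("t1.sp", "t2.d1"))  # track-major layout
  expect_equal(unflatten_tensor(v, 4, 10), t1$matrix)
  expect_error(assemble_tensor(lin, sp[1:3], "G1", 10, 5000, FALSE),
               "row mismatch")
  expect_error(assemble_tensor(lin[, 1:19], sp, "G1", 10, 5000, FALSE), "2K")
})

test_that("tensor archives round-trip exactly and enforce gene keys", {
  fx <- small_dataset()
  arch <- fx$archive
  f <- withr::local_tempfile(fileext = ".rds")
  write_tensor_archive(arch, f)
  back <- read_tensor_archive(f)
  expect_identical(back, arch)
  expect_error(archive_tensor(arch, "NOPE"), "not in archive")
  expect_error(feature_matrix(arch, c("G0001", "NOPE")), "NOPE")

  m <- feature_matrix(arch)
  expect_equal(dim(m), c(nrow(arch$genes), 20 * 21))
  mb <- feature_matrix(arch, spatial = FALSE)
  expect_equal(ncol(mb), 20 * 20)       # spatial columns removed, not zeroed
  expect_false(any(grepl("\\.sp$", colnames(mb))))
  # flattened rows agree with per-gene tensors
  g1 <- arch$genes$gene_id[1]
  expect_equal(m[g1, ], flatten_tensor(archive_tensor(arch, g1)))
})

test_that("an all-zero track store yields all-zero tensors", {
  lens <- c(chr1 = 5e5, chr8 = 5e5)
  genes <- data.frame(gene_id = c("A", "B"), chrom = c("chr1", "chr8"),
                      tss = c(100000L, 300000L), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  cs <- contact_set(data.frame(chrom = "chr1", start1 = 100000, end1 = 105000,
                               start2 = 400000, end2 = 405000, count = 3), 5000)
  p <- track_predictor(constant_store(0, 3, lens))
  arch <- build_tensor_archive(genes, cs, p, verbose = FALSE)
  expect_true(all(feature_matrix(arch) == 0))
})
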