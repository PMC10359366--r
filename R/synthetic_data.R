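#' Configuration of the synthetic study generator
#'
#' Defines a download-free dataset with the statistical structure the
#' spatial expression model assumes: genes with well-separated TSSs on a
#' few chromosomes (the holdout chromosome among them), smooth per-track
#' signal, binned intra-chromosomal contacts in which a fraction of genes
#' carries planted TSS-anchored loops to distal regions outside the 20 kb
#' linear scope, and log-space expression that depends on both the local
#' window signal and the looped distal signal:
#' `y = beta_lin * s_lin + beta_sp * s_sp + eps`, `eps ~ N(0, noise_sd)`.
#'
#' `s_lin` is the standardized mean track signal over the gene's +/-20 kb
#' window; `s_sp` the standardized summed track signal over the gene's
#' qualifying planted loop anchors (count >= 2, outside the linear scope),
#' both computed with the same averaging predictor the pipeline uses, and 0
#' for genes without qualifying loops. Decoy loops — distal ones observed
#' only once, and near ones inside the linear scope — are planted alongside
#' and never contribute, so the pipeline's count and scope filters are
#' exercised end to end.
#'
#' @param n_genes number of genes.
#' @param chrom_lengths named chromosome lengths (bp); the default five
#'   2 Mb chromosomes include the `chr8` holdout.
#' @param n_tracks tracks in the synthetic store (desk-scale default 20;
#'   the full-scale compendium has 2002).
#' @param K decay scales per side.
#' @param resolution contact-matrix bin width (bp).
#' @param loop_prob probability that a gene carries planted distal loops.
#' @param n_loops planted qualifying loops per looped gene.
#' @param loop_distance range (bp) of planted loop distances from the TSS;
#'   must clear the linear scope by at least two bins.
#' @param count_range range of counts for qualifying loops (>= 2).
#' @param decoy_low_prob probability of an extra distal loop with count 1.
#' @param decoy_near_prob probability of an extra in-scope loop.
#' @param beta_lin,beta_sp effect sizes of the linear and spatial signals.
#' @param noise_sd SD of the log-space expression noise.
#' @param n_tissues pseudo-tissues (independent noise draws, shared signal).
#' @param step track-store step width (bp).
#' @param min_spacing minimum TSS spacing (bp).
#' @param linear_scope half-width of the linear scope (bp).
#' @param pseudocount pseudocount of the log target transform.
#' @param seed master seed; every random draw flows from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 300L,
                         chrom_lengths = c(chr1 = 2e6, chr2 = 2e6,
                                           chr3 = 2e6, chr5 = 2e6,
                                           chr8 = 2e6),
                         n_tracks = 20L, K = 10L, resolution = 5000L,
                         loop_prob = 0.5, n_loops = 2L,
                         loop_distance = c(50000L, 500000L),
                         count_range = c(2L, 5L),
                         decoy_low_prob = 0.5, decoy_near_prob = 0.5,
                         beta_lin = 1, beta_sp = 1, noise_sd = 0.5,
                         n_tissues = 1L, step = 200L,
                         min_spacing = 30000L, linear_scope = 20000L,
                         pseudocount = 1e-4, seed = 0L) {
  stopifnot(n_genes >= 1, length(chrom_lengths) >= 1,
            !is.null(names(chrom_lengths)),
            loop_prob >= 0, loop_prob <= 1, n_loops >= 1,
            count_range[1] >= 2, count_range[2] >= count_range[1],
            noise_sd >= 0, n_tissues >= 1)
  if (loop_distance[1] <= linear_scope + 2 * resolution)
    stop("loop_distance must clear the linear scope by at least two bins")
  if (resolution %% step != 0 && step %% resolution != 0)
    message("synth_config: resolution and step are not nested; fine, but ",
            "region snapping will truncate")
  structure(list(n_genes = as.integer(n_genes),
                 chrom_lengths = chrom_lengths, n_tracks = as.integer(n_tracks),
                 K = as.integer(K), resolution = as.integer(resolution),
                 loop_prob = loop_prob, n_loops = as.integer(n_loops),
                 loop_distance = as.integer(loop_distance),
                 count_range = as.integer(count_range),
                 decoy_low_prob = decoy_low_prob,
                 decoy_near_prob = decoy_near_prob,
                 beta_lin = beta_lin, beta_sp = beta_sp,
                 noise_sd = noise_sd, n_tissues = as.integer(n_tissues),
                 step = as.integer(step),
                 min_spacing = as.integer(min_spacing),
                 linear_scope = as.integer(linear_scope),
                 pseudocount = pseudocount, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic study dataset
#'
#' Produces genes, contacts, a track store, an expression matrix and the
#' truth record described in [synth_config()]. The generation is a pure
#' function of the configuration: the same config yields byte-identical
#' fixtures.
#'
#' @param cfg a [synth_config()].
#' @return object of class `synthetic_dataset` with elements `genes`
#'   (gene table), `contacts` (BEDPE-layout data.frame), `contact_set`,
#'   `store` ([track_store()]), `expression` (matrix), `truth`
#'   (data.frame with per-gene `s_lin`, `s_sp`, `has_loop`, `n_regions`,
#'   `y`) and `config`.
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  margin <- 22000L  # window half-width (20 kb) + predictor context + slack
  if (any(cfg$chrom_lengths < 2 * margin + cfg$min_spacing))
    stop("chromosomes too short for the TSS window; ",
         "increase chrom_lengths")
  res <- cfg$resolution

  placed <- with_seed(cfg$seed, {
    # round-robin allocation of genes to chromosomes
    chroms <- names(cfg$chrom_lengths)
    alloc <- table(factor(chroms[(seq_len(cfg$n_genes) - 1L) %%
                                   length(chroms) + 1L], levels = chroms))
    genes <- NULL
    for (ch in chroms) {
      n_c <- as.integer(alloc[[ch]])
      if (n_c == 0) next
      usable <- cfg$chrom_lengths[[ch]] - 2 * margin
      w <- floor(usable / n_c)
      if (w < cfg$min_spacing)
        stop("cannot place ", n_c, " genes on ", ch, " at >= ",
             cfg$min_spacing, " bp spacing; increase chrom_lengths")
      jitter <- sample.int(w - cfg$min_spacing + 1L, n_c,
                           replace = TRUE) - 1L
      tss <- as.integer(margin + (seq_len(n_c) - 1L) * w + jitter)
      genes <- rbind(genes, data.frame(
        chrom = ch, tss = tss,
        strand = sample(c("+", "-"), n_c, replace = TRUE),
        stringsAsFactors = FALSE))
    }
    genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "chrom", "tss", "strand")]

    # planted loops
    loops <- list()
    truth_regions <- vector("list", nrow(genes))
    has_loop <- stats::runif(nrow(genes)) < cfg$loop_prob
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      len <- cfg$chrom_lengths[[g$chrom]]
      bin1 <- (g$tss %/% res) * res
      draw_distal_bin <- function() {
        d <- stats::runif(1, cfg$loop_distance[1], cfg$loop_distance[2])
        dirs <- c(if (g$tss + d + res <= len) 1L,
                  if (g$tss - d >= 0) -1L)
        if (is.null(dirs)) return(NULL)
        dir <- if (length(dirs) == 1) dirs else sample(dirs, 1)
        (as.integer(g$tss + dir * d) %/% res) * res
      }
      regs <- integer(0)
      if (has_loop[i]) {
        for (k in seq_len(cfg$n_loops)) {
          b2 <- draw_distal_bin()
          if (is.null(b2))
            stop("cannot place a distal loop for ", g$gene_id,
                 "; increase chrom_lengths")
          cnt <- sample(seq(cfg$count_range[1], cfg$count_range[2]), 1)
          loops[[length(loops) + 1L]] <-
            data.frame(chrom = g$chrom, bin1 = bin1, bin2 = b2, count = cnt)
          regs <- c(regs, b2)
        }
      }
      regs <- sort(unique(regs))
      # decoy: distal but seen only once (below the count threshold)
      if (stats::runif(1) < cfg$decoy_low_prob) {
        for (try in 1:10) {
          b2 <- draw_distal_bin()
          if (!is.null(b2) && !(b2 %in% regs)) {
            loops[[length(loops) + 1L]] <-
              data.frame(chrom = g$chrom, bin1 = bin1, bin2 = b2, count = 1L)
            break
          }
        }
      }
      # decoy: well observed but inside the linear scope
      if (stats::runif(1) < cfg$decoy_near_prob) {
        dir <- sample(c(-1L, 1L), 1)
        b2 <- ((g$tss + dir * 10000L) %/% res) * res
        if (b2 >= 0 && b2 + res <= len && b2 != bin1)
          loops[[length(loops) + 1L]] <-
            data.frame(chrom = g$chrom, bin1 = bin1, bin2 = b2,
                       count = sample(2:4, 1))
      }
      truth_regions[[i]] <- regs
    }
    list(genes = genes, loops = loops, truth_regions = truth_regions,
         has_loop = has_loop)
  })
  genes <- validate_gene_table(placed$genes)

  contacts <- if (length(placed$loops) > 0) {
    l <- do.call(rbind, placed$loops)
    data.frame(chrom1 = l$chrom, start1 = l$bin1, end1 = l$bin1 + res,
               chrom2 = l$chrom, start2 = l$bin2, end2 = l$bin2 + res,
               count = l$count, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom1 = character(0), start1 = integer(0),
               end1 = integer(0), chrom2 = character(0),
               start2 = integer(0), end2 = integer(0), count = integer(0))
  }
  cs <- contact_set(data.frame(chrom = contacts$chrom1,
                               start1 = contacts$start1,
                               end1 = contacts$end1,
                               start2 = contacts$start2,
                               end2 = contacts$end2,
                               count = contacts$count,
                               stringsAsFactors = FALSE), res)

  store <- synth_track_store(cfg$chrom_lengths, n_tracks = cfg$n_tracks,
                             step = cfg$step, seed = cfg$seed + 1L)
  predictor <- track_predictor(store)

  # truth signals: the effective qualifying regions of each gene under the
  # count / anchor / scope rules, aggregated with the same averaging
  # predictor the pipeline uses
  s_lin_raw <- numeric(nrow(genes))
  s_sp_raw <- numeric(nrow(genes))
  n_regions <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    grid <- build_bin_grid(g, chrom_length = cfg$chrom_lengths[[g$chrom]])
    s_lin_raw[i] <- mean(window_signal(grid, predictor))
    sel <- select_spatial_regions(cs, g, linear_scope = cfg$linear_scope,
                                  min_count = 2L)
    n_regions[i] <- nrow(sel$regions)
    if (!sel$used_fallback)
      s_sp_raw[i] <- mean(spatial_feature(sel, predictor, grid))
  }
  s_lin <- standardize(s_lin_raw)
  looped <- n_regions > 0
  s_sp <- numeric(nrow(genes))
  if (sum(looped) >= 2) s_sp[looped] <- standardize(s_sp_raw[looped])

  y <- with_seed(cfg$seed + 2L, {
    signal <- cfg$beta_lin * s_lin + cfg$beta_sp * s_sp
    sapply(seq_len(cfg$n_tissues), function(t)
      signal + stats::rnorm(length(signal), 0, cfg$noise_sd))
  })
  y <- matrix(y, nrow = nrow(genes))
  expression <- pmax(exp(y) - cfg$pseudocount, 0)  # keeps matrix dims
  rownames(expression) <- genes$gene_id
  colnames(expression) <- paste0("tissue", seq_len(cfg$n_tissues))

  truth <- data.frame(genes, has_loop = looped, n_regions = n_regions,
                      s_lin = s_lin, s_sp = s_sp, y = y[, 1],
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, contacts = contacts, contact_set = cs,
                 store = store, expression = expression, truth = truth,
                 config = cfg),
            class = "synthetic_dataset")
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (length(x) < 2 || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic study dataset:", nrow(x$genes), "genes on",
      length(x$config$chrom_lengths), "chromosomes,",
      nrow(x$contacts), "planted contacts (",
      sum(x$truth$has_loop), "genes with qualifying loops),",
      x$config$n_tracks, "tracks,", ncol(x$expression), "pseudo-tissue(s)\n")
  invisible(x)
}

#' Write a synthetic dataset to fixture files
#'
#' Writes exactly the formats the pipeline reads: `genes.bed` (BED6),
#' `contacts.bedpe`, `tracks.rds` (track store), `expression.tsv`,
#' `tissue_mapping.tsv`, `truth.tsv`, plus `manifest.tsv` listing every
#' file with its MD5 checksum. Re-reading the files through the package's
#' own readers reconstructs the dataset.
#'
#' @param ds a [synth_generate()] result.
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture <- function(ds, dir, overwrite = FALSE) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite)
    stop("directory not empty (use overwrite = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(dir, "genes.bed"),
             contacts = file.path(dir, "contacts.bedpe"),
             tracks = file.path(dir, "tracks.rds"),
             expression = file.path(dir, "expression.tsv"),
             mapping = file.path(dir, "tissue_mapping.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_gene_table(ds$genes, paths["genes"], format = "bed6")
  utils::write.table(ds$contacts, paths["contacts"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_track_store(ds$store, paths["tracks"])
  write_expression_matrix(ds$expression, paths["expression"])
  writeLines(paste0("synthetic=", colnames(ds$expression)[1]),
             paths["mapping"])
  utils::write.table(ds$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, manifest = manifest_path))
}
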