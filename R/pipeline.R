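#' Read and validate a pipeline configuration
#'
#' The pipeline is configured by a YAML file with five sections —
#' `paths` (genes, contacts, tracks, expression, mapping, workdir),
#' `features` (K, lambdas, min_count, linear_scope, resolution,
#' anchor_mode), `model` (booster, n_rounds, learning_rate, max_depth,
#' subsample, colsample), `split` (test_chrom, excluded_chroms) and `runs`
#' (n_runs, base_seed) — plus an optional `simulate` section holding
#' [synth_config()] fields. Unknown sections or keys are rejected before
#' any stage runs.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  known <- list(
    paths = c("genes", "contacts", "tracks", "expression", "mapping",
              "workdir"),
    features = c("K", "lambdas", "min_count", "linear_scope", "resolution",
                 "anchor_mode"),
    model = c("booster", "n_rounds", "learning_rate", "max_depth",
              "subsample", "colsample"),
    split = c("test_chrom", "excluded_chroms"),
    runs = c("n_runs", "base_seed"),
    simulate = c("n_genes", "chrom_lengths", "n_tracks", "K", "resolution",
                 "loop_prob", "n_loops", "loop_distance", "count_range",
                 "decoy_low_prob", "decoy_near_prob", "beta_lin", "beta_sp",
                 "noise_sd", "n_tissues", "step", "min_spacing",
                 "linear_scope", "pseudocount", "seed"))
  bad <- setdiff(names(cfg), names(known))
  if (length(bad) > 0) stop("unknown config section: ", bad[1])
  for (sec in names(cfg)) {
    extra <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (length(extra) > 0)
      stop("unknown key in config section '", sec, "': ", extra[1])
  }
  if (is.null(cfg$paths$workdir)) stop("config needs paths$workdir")
  structure(cfg, class = "pipeline_config")
}

cfg_get <- function(cfg, sec, key, default) {
  v <- cfg[[sec]][[key]]
  if (is.null(v)) default else v
}

#' Pipeline stage: simulate a synthetic fixture
#'
#' Wraps [synth_generate()] + [write_fixture()] using the config's
#' `simulate` section and writes the fixture into the workdir; the config's
#' input paths are then expected to point at these files.
#'
#' @param cfg a [pipeline_config()].
#' @param overwrite overwrite an existing fixture directory.
#' @return fixture directory path, invisibly.
#' @export
cmd_simulate <- function(cfg, overwrite = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- cfg$simulate
  if (!is.null(sim$chrom_lengths))
    sim$chrom_lengths <- unlist(sim$chrom_lengths)
  scfg <- do.call(synth_config, if (is.null(sim)) list() else sim)
  ds <- synth_generate(scfg)
  out <- file.path(cfg$paths$workdir, "fixture")
  write_fixture(ds, out, overwrite = overwrite)
  message("simulated fixture: ", nrow(ds$genes), " genes, ",
          nrow(ds$contacts), " contacts -> ", out)
  invisible(out)
}

#' Pipeline stage: build the tensor archive
#'
#' Reads genes, contacts and the track store through the package readers,
#' builds one tensor per gene and writes the archive into the workdir.
#' An existing archive is reused unless `force = TRUE`.
#'
#' @param cfg a [pipeline_config()].
#' @param force rebuild even if the archive exists.
#' @return archive path, invisibly.
#' @export
cmd_build_tensors <- function(cfg, force = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- file.path(cfg$paths$workdir, "tensors.rds")
  if (file.exists(out) && !force) {
    message("tensor archive exists, skipping (use force = TRUE): ", out)
    return(invisible(out))
  }
  genes <- read_gene_table(cfg$paths$genes)
  resolution <- cfg_get(cfg, "features", "resolution", 5000L)
  cs <- read_bedpe(cfg$paths$contacts, resolution)
  store <- read_track_store(cfg$paths$tracks)
  predictor <- track_predictor(store)
  K <- cfg_get(cfg, "features", "K", 10L)
  lambdas <- cfg_get(cfg, "features", "lambdas", 200 * 2^(seq_len(K) - 1))
  basis <- decay_basis(K = K, lambdas = lambdas)
  message("building tensors: ", nrow(genes), " genes, ",
          nrow(cs$contacts), " contacts at ", resolution, " bp")
  archive <- build_tensor_archive(
    genes, cs, predictor, basis,
    linear_scope = cfg_get(cfg, "features", "linear_scope", 20000L),
    min_count = cfg_get(cfg, "features", "min_count", 2L),
    anchor_mode = cfg_get(cfg, "features", "anchor_mode", "point"))
  dir.create(cfg$paths$workdir, showWarnings = FALSE, recursive = TRUE)
  write_tensor_archive(archive, out)
  invisible(out)
}

#' Pipeline stage: repeated training and evaluation of one arm
#'
#' Loads the tensor archive and expression matrix, splits by chromosome,
#' and runs the repeated fit/evaluate cycle for the requested arm —
#' `"spatial"` (full tensors) or `"baseline"` (spatial column dropped).
#' Metrics are written to `metrics_<arm>.tsv` in the workdir.
#'
#' @param cfg a [pipeline_config()].
#' @param arm `"spatial"` or `"baseline"`.
#' @return path of the metrics TSV, invisibly.
#' @export
cmd_train_eval <- function(cfg, arm = c("spatial", "baseline")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  arm <- match.arg(arm)
  archive <- read_tensor_archive(file.path(cfg$paths$workdir, "tensors.rds"))
  expr <- read_expression_matrix(cfg$paths$expression)
  tissue <- colnames(expr)[1]
  if (!is.null(cfg$paths$mapping) && file.exists(cfg$paths$mapping)) {
    map <- read_tissue_mapping(cfg$paths$mapping, expr)
    tissue <- map[[1]]
  }
  split <- split_spec(
    test_chrom = cfg_get(cfg, "split", "test_chrom", "chr8"),
    excluded_chroms = cfg_get(cfg, "split", "excluded_chroms",
                              c("chrX", "chrY")))
  mcfg <- model_config(
    booster = cfg_get(cfg, "model", "booster", "tree"),
    n_rounds = cfg_get(cfg, "model", "n_rounds", 200L),
    learning_rate = cfg_get(cfg, "model", "learning_rate", 0.05),
    max_depth = cfg_get(cfg, "model", "max_depth", 6L),
    subsample = cfg_get(cfg, "model", "subsample", 0.8),
    colsample = cfg_get(cfg, "model", "colsample", 0.8))
  genes <- archive$genes[archive$genes$gene_id %in% rownames(expr), ,
                         drop = FALSE]
  sp <- chromosome_split(genes, split)
  y <- transform_target(expr[genes$gene_id, tissue])
  names(y) <- genes$gene_id
  spatial <- arm == "spatial"
  ftr <- feature_matrix(archive, sp$train_ids, spatial = spatial)
  fte <- feature_matrix(archive, sp$test_ids, spatial = spatial)
  message("train-eval [", arm, "]: ", length(sp$train_ids), " train / ",
          length(sp$test_ids), " test / ", length(sp$excluded_ids),
          " excluded genes, ", ncol(ftr), " features, tissue ", tissue)
  runs <- repeated_runs(ftr, y[sp$train_ids], fte, y[sp$test_ids], mcfg,
                        n_runs = cfg_get(cfg, "runs", "n_runs", 10L),
                        base_seed = cfg_get(cfg, "runs", "base_seed", 0L))
  runs <- data.frame(arm = arm, runs, stringsAsFactors = FALSE)
  out <- file.path(cfg$paths$workdir, paste0("metrics_", arm, ".tsv"))
  utils::write.table(runs, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Pipeline stage: compare arms
#'
#' Reads the per-run metric TSVs of both arms, runs the Welch /
#' Bonferroni comparison via [grouped_comparison()] and writes
#' `comparison.tsv` (per experiment) and `comparison_groups.tsv` in the
#' workdir.
#'
#' @param cfg a [pipeline_config()].
#' @param metric metric column to compare (default `"scc"`).
#' @param experiment,group labels for this run (defaults `"synthetic"`).
#' @return the [grouped_comparison()] result, invisibly.
#' @export
cmd_compare <- function(cfg, metric = "scc", experiment = "synthetic",
                        group = "synthetic") {
  stopifnot(inherits(cfg, "pipeline_config"))
  paths <- file.path(cfg$paths$workdir,
                     paste0("metrics_", c("spatial", "baseline"), ".tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) stop("missing metrics arm: ", missing[1])
  runs <- do.call(rbind, lapply(paths, utils::read.table, header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE))
  runs$experiment <- experiment
  runs$group <- group
  cmpres <- grouped_comparison(runs, metric = metric)
  utils::write.table(cmpres$per_experiment,
                     file.path(cfg$paths$workdir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cmpres$per_group,
                     file.path(cfg$paths$workdir, "comparison_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("comparison [", metric, "]: improvement ",
          signif(cmpres$per_experiment$improvement[1], 4), ", p_adj ",
          signif(cmpres$per_experiment$p_adj[1], 3))
  invisible(cmpres)
}
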