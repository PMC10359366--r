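#' Chromosome-holdout split specification
#'
#' The evaluation design holds out one whole chromosome for testing —
#' chromosome 8 by default, a chromosome close to the mean size — so that
#' no test gene's features or target can leak into training. The sex
#' chromosomes are excluded from the study entirely.
#'
#' @param test_chrom chromosome used exclusively for testing.
#' @param excluded_chroms chromosomes dropped from the study.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(test_chrom = "chr8",
                       excluded_chroms = c("chrX", "chrY")) {
  if (test_chrom %in% excluded_chroms)
    stop("test_chrom must not be in excluded_chroms")
  structure(list(test_chrom = test_chrom,
                 excluded_chroms = excluded_chroms),
            class = "split_spec")
}

#' Split genes into train / test / excluded by chromosome
#'
#' @param genes gene table.
#' @param spec a [split_spec()].
#' @return list with character vectors `train_ids`, `test_ids`,
#'   `excluded_ids`; the three are disjoint and their union is all genes.
#' @export
chromosome_split <- function(genes, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  genes <- validate_gene_table(genes)
  excluded <- genes$chrom %in% spec$excluded_chroms
  test <- !excluded & genes$chrom == spec$test_chrom
  train <- !excluded & !test
  if (!any(test))
    stop("no genes on test chromosome ", spec$test_chrom)
  list(train_ids = genes$gene_id[train],
       test_ids = genes$gene_id[test],
       excluded_ids = genes$gene_id[excluded])
}

#' Regressor configuration
#'
#' The expression regressor is a gradient-boosted ensemble with a
#' squared-error objective: boosted trees (`booster = "tree"`, the spatial
#' model's configuration) or a boosted linear model (`booster = "linear"`,
#' the lineage baseline option). Trees are grown with the CPU histogram
#' method on a single thread so fits are exactly reproducible from the
#' seed. Row and column subsampling (defaults 0.8) give independent
#' training repetitions genuine run-to-run variability, which the
#' repeated-training significance tests rely on.
#'
#' @param booster `"tree"` or `"linear"`.
#' @param n_rounds boosting rounds.
#' @param learning_rate shrinkage per round.
#' @param max_depth tree depth (tree booster only).
#' @param subsample,colsample row / column subsampling per tree.
#' @param seed RNG seed for the fit.
#' @param nthread threads (1 keeps fits bit-reproducible).
#' @return object of class `model_config`.
#' @export
model_config <- function(booster = c("tree", "linear"), n_rounds = 200L,
                         learning_rate = 0.05, max_depth = 6L,
                         subsample = 0.8, colsample = 0.8, seed = 0L,
                         nthread = 1L) {
  booster <- match.arg(booster)
  stopifnot(n_rounds >= 1, learning_rate > 0, max_depth >= 1,
            subsample > 0, subsample <= 1, colsample > 0, colsample <= 1)
  structure(list(booster = booster, objective = "reg:squarederror",
                 n_rounds = as.integer(n_rounds),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 subsample = subsample, colsample = colsample,
                 seed = as.integer(seed), nthread = as.integer(nthread)),
            class = "model_config")
}

xgb_params <- function(cfg) {
  p <- list(objective = cfg$objective, nthread = cfg$nthread,
            seed = cfg$seed)
  if (cfg$booster == "tree") {
    p <- c(p, list(booster = "gbtree", tree_method = "hist",
                   eta = cfg$learning_rate, max_depth = cfg$max_depth,
                   subsample = cfg$subsample,
                   colsample_bytree = cfg$colsample))
  } else {
    p <- c(p, list(booster = "gblinear", eta = cfg$learning_rate))
  }
  p
}

#' Fit the expression regressor
#'
#' Fits the gradient-boosted regressor of log expression on a flattened
#' feature matrix. The fit is deterministic given the data, the
#' configuration seed and single-thread mode, and the returned model
#' records the feature layout so predictions on mismatched matrices are
#' refused.
#'
#' @param features numeric matrix `genes x features` with column names
#'   (the layout) and row names (gene ids).
#' @param targets numeric vector of log-expression targets aligned with the
#'   rows of `features`.
#' @param cfg a [model_config()].
#' @return object of class `expression_model`.
#' @export
fit_expression_model <- function(features, targets, cfg = model_config()) {
  stopifnot(is.matrix(features), inherits(cfg, "model_config"))
  if (nrow(features) != length(targets))
    stop("features and targets are misaligned: ", nrow(features),
         " rows vs ", length(targets), " targets")
  bad <- which(!is.finite(features), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite feature for gene ", rownames(features)[bad[1, 1]],
         ", column ", colnames(features)[bad[1, 2]])
  if (any(!is.finite(targets))) stop("non-finite target")
  dtrain <- xgboost::xgb.DMatrix(features, label = targets)
  fit <- with_seed(cfg$seed,
                   xgboost::xgb.train(params = xgb_params(cfg), data = dtrain,
                                      nrounds = cfg$n_rounds, verbose = 0))
  structure(list(booster = fit, feature_names = colnames(features),
                 config = cfg),
            class = "expression_model")
}

#' @export
print.expression_model <- function(x, ...) {
  cat("Expression regressor: gradient-boosted", x$config$booster,
      "model,", length(x$feature_names), "features,",
      x$config$n_rounds, "rounds (seed", paste0(x$config$seed, ")"), "\n")
  invisible(x)
}

#' Predict log expression
#'
#' @param object an [fit_expression_model()] result.
#' @param features matrix with exactly the training feature layout
#'   (checked by column names).
#' @param ... unused.
#' @return numeric vector of predicted log expression, named by gene.
#' @export
predict.expression_model <- function(object, features, ...) {
  stopifnot(is.matrix(features))
  if (nrow(features) == 0)
    return(stats::setNames(numeric(0), character(0)))
  if (is.null(colnames(features)) ||
      !identical(colnames(features), object$feature_names))
    stop("feature layout mismatch: prediction matrix does not match ",
         "the training layout")
  p <- predict(object$booster, xgboost::xgb.DMatrix(features))
  stats::setNames(as.numeric(p), rownames(features))
}

#' Save / load an expression model
#'
#' The booster is stored in the boosting library's native UBJSON format with
#' a JSON sidecar (`<path>.meta.json`) recording the feature layout and the
#' fit configuration; loading restores a model whose predictions are
#' identical to the original.
#'
#' @param model an `expression_model`.
#' @param path file path for the booster (sidecar derives from it).
#' @return `path` invisibly (save); the model (load).
#' @export
save_expression_model <- function(model, path) {
  stopifnot(inherits(model, "expression_model"))
  xgboost::xgb.save(model$booster, path)
  meta <- list(feature_names = model$feature_names,
               config = unclass(model$config))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_expression_model
#' @export
load_expression_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(model_config, c(
    list(booster = meta$config$booster),
    meta$config[c("n_rounds", "learning_rate", "max_depth", "subsample",
                  "colsample", "seed", "nthread")]))
  structure(list(booster = xgboost::xgb.load(path),
                 feature_names = meta$feature_names, config = cfg),
            class = "expression_model")
}

#' Repeated training runs
#'
#' Repeats the fit/evaluate cycle `n_runs` times, run `i` using seed
#' `base_seed + i - 1`, and reports the test-set Spearman and Pearson
#' correlations and RMSE per run. At full scale this repetition (the study
#' design used 1000 repetitions per cell line) is what turns single-run
#' score differences into testable distributions.
#'
#' @param train_features,train_targets training data.
#' @param test_features,test_targets held-out data.
#' @param cfg a [model_config()]; its seed is overridden per run.
#' @param n_runs number of repetitions.
#' @param base_seed seed of the first run.
#' @return data.frame with one row per run: `run, seed, scc, pcc, rmse`.
#' @export
repeated_runs <- function(train_features, train_targets, test_features,
                          test_targets, cfg = model_config(), n_runs = 10L,
                          base_seed = 0L) {
  stopifnot(n_runs >= 1)
  out <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    run_cfg <- cfg
    run_cfg$seed <- as.integer(base_seed + i - 1L)
    m <- fit_expression_model(train_features, train_targets, run_cfg)
    p <- predict(m, test_features)
    out[[i]] <- data.frame(run = i, seed = run_cfg$seed,
                           scc = scc(p, test_targets),
                           pcc = pcc(p, test_targets),
                           rmse = rmse(p, test_targets))
  }
  do.call(rbind, out)
}
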