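#' Fit the spatial expression model on a tensor archive
#'
#' The top-level fitting interface: joins a tensor archive with an
#' expression matrix, log-transforms the chosen tissue's values into the
#' regression target, splits genes by chromosome holdout, fits the
#' gradient-boosted regressor on the training chromosomes and evaluates on
#' the held-out chromosome. With `spatial = FALSE` the spatial column is
#' removed from the feature layout, giving the baseline arm without any
#' three-dimensional contact information.
#'
#' @param archive a [build_tensor_archive()] result (or a path to one
#'   written by [write_tensor_archive()]).
#' @param expression expression matrix from [read_expression_matrix()].
#' @param tissue tissue column to model (default: first column).
#' @param spatial include the spatial feature column?
#' @param split a [split_spec()].
#' @param config a [model_config()].
#' @param pseudocount pseudocount of the log target transform.
#' @return object of class `spex_fit` with the fitted model, the split,
#'   test-set predictions and metrics.
#' @export
spex <- function(archive, expression, tissue = NULL, spatial = TRUE,
                 split = split_spec(), config = model_config(),
                 pseudocount = 1e-4) {
  if (is.character(archive)) archive <- read_tensor_archive(archive)
  stopifnot(inherits(archive, "tensor_archive"), is.matrix(expression))
  if (is.null(tissue)) tissue <- colnames(expression)[1]
  if (!tissue %in% colnames(expression))
    stop("tissue not in expression matrix: ", tissue)
  genes <- archive$genes[archive$genes$gene_id %in% rownames(expression), ,
                         drop = FALSE]
  if (nrow(genes) == 0) stop("no overlap between archive and expression genes")
  sp <- chromosome_split(genes, split)
  y <- transform_target(expression[genes$gene_id, tissue], pseudocount)
  names(y) <- genes$gene_id
  ftr <- feature_matrix(archive, sp$train_ids, spatial = spatial)
  fte <- feature_matrix(archive, sp$test_ids, spatial = spatial)
  model <- fit_expression_model(ftr, y[sp$train_ids], config)
  pred <- predict(model, fte)
  obs <- y[sp$test_ids]
  structure(list(model = model, archive_meta = list(
                   n_tracks = archive$n_tracks, K = archive$K,
                   resolution = archive$resolution,
                   fallback_rate = mean(archive$fallback)),
                 spatial = spatial, split = sp, split_spec = split,
                 tissue = tissue, pseudocount = pseudocount,
                 observed = obs, predicted = pred,
                 metrics = c(scc = scc(pred, obs), pcc = pcc(pred, obs),
                             rmse = rmse(pred, obs))),
            class = "spex_fit")
}

#' @export
print.spex_fit <- function(x, ...) {
  cat("Spatial expression model (",
      if (x$spatial) "spatial arm" else "baseline arm, no spatial column",
      ")\n", sep = "")
  cat("  tissue:", x$tissue, "| train genes:", length(x$split$train_ids),
      "| test genes:", length(x$split$test_ids),
      "(", x$split_spec$test_chrom, ") | excluded:",
      length(x$split$excluded_ids), "\n")
  cat("  test metrics: SCC", signif(x$metrics["scc"], 4),
      "| PCC", signif(x$metrics["pcc"], 4),
      "| RMSE", signif(x$metrics["rmse"], 4), "\n")
  invisible(x)
}

#' @export
summary.spex_fit <- function(object, ...) {
  r <- residuals(object)
  out <- list(metrics = object$metrics,
              spatial = object$spatial,
              tissue = object$tissue,
              n_train = length(object$split$train_ids),
              n_test = length(object$split$test_ids),
              n_excluded = length(object$split$excluded_ids),
              fallback_rate = object$archive_meta$fallback_rate,
              residual_summary = summary(r),
              residual_sd = stats::sd(r))
  class(out) <- "summary.spex_fit"
  out
}

#' @export
print.summary.spex_fit <- function(x, ...) {
  cat("Spatial expression model summary (",
      if (x$spatial) "spatial" else "baseline", " arm)\n", sep = "")
  cat("  tissue:", x$tissue, "\n")
  cat("  genes: ", x$n_train, " train / ", x$n_test, " test / ",
      x$n_excluded, " excluded; fallback rate ",
      round(100 * x$fallback_rate, 1), "%\n", sep = "")
  cat("  test SCC ", signif(x$metrics["scc"], 4),
      ", PCC ", signif(x$metrics["pcc"], 4),
      ", RMSE ", signif(x$metrics["rmse"], 4), "\n", sep = "")
  cat("  test residuals (observed - predicted), SD ",
      signif(x$residual_sd, 4), ":\n", sep = "")
  print(x$residual_summary)
  invisible(x)
}

#' Predict from a fitted spatial expression model
#'
#' @param object a [spex()] fit.
#' @param archive a tensor archive to predict for (default: the test genes
#'   of the training archive are already in `object$predicted`).
#' @param gene_ids genes to predict (default: all genes in `archive`).
#' @param ... unused.
#' @return gene-named vector of predicted log expression.
#' @export
predict.spex_fit <- function(object, archive = NULL, gene_ids = NULL, ...) {
  if (is.null(archive)) return(object$predicted)
  if (is.character(archive)) archive <- read_tensor_archive(archive)
  m <- feature_matrix(archive, gene_ids, spatial = object$spatial)
  predict(object$model, m)
}

#' Test-set residuals (observed minus predicted)
#'
#' @param object a [spex()] fit.
#' @param ... unused.
#' @return gene-named residual vector on the held-out chromosome.
#' @export
residuals.spex_fit <- function(object, ...) {
  object$observed - object$predicted
}

#' @export
fitted.spex_fit <- function(object, ...) object$predicted

#' Observed-versus-predicted plot on the held-out chromosome
#'
#' @param x a [spex()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spex_fit <- function(x, ...) {
  graphics::plot(x$predicted, x$observed,
                 xlab = "predicted log expression",
                 ylab = "observed log expression",
                 main = sprintf("%s arm: test SCC %.3f",
                                if (x$spatial) "spatial" else "baseline",
                                x$metrics["scc"]), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
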