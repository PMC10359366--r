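#' Prediction-quality metrics
#'
#' Spearman rank correlation (`scc`, average ranks for ties), Pearson
#' correlation (`pcc`) and root-mean-square error (`rmse`) between predicted
#' and observed values. A constant vector makes the correlations undefined;
#' that is reported as an error, never silently as zero.
#'
#' @param pred,obs equal-length finite numeric vectors (length >= 3 for the
#'   correlations).
#' @return a single numeric value.
#' @export
scc <- function(pred, obs) {
  check_metric_input(pred, obs, min_n = 3)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(pred, obs, method = "spearman")
}

#' @rdname scc
#' @export
pcc <- function(pred, obs) {
  check_metric_input(pred, obs, min_n = 3)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(pred, obs, method = "pearson")
}

#' @rdname scc
#' @export
rmse <- function(pred, obs) {
  check_metric_input(pred, obs, min_n = 1)
  sqrt(mean((pred - obs)^2))
}

check_metric_input <- function(pred, obs, min_n) {
  if (length(pred) != length(obs))
    stop("pred and obs must have equal length")
  if (length(pred) < min_n)
    stop("need at least ", min_n, " observations")
  if (any(!is.finite(pred)) || any(!is.finite(obs)))
    stop("non-finite value in metric input")
  invisible(TRUE)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom, two-sided.
#' The degenerate case of two zero-variance samples with equal means is
#' reported as `t = 0, p = 1` by convention (and logged); zero-variance
#' samples with different means give `p = 0`.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      message("welch_test: both samples constant and equal; p = 1 by convention")
      return(list(t = 0, df = NA_real_, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` for a family of `m` tests; `m` may exceed the
#' number of p-values supplied (tests counted but not reported here).
#'
#' @param pvals p-values in `[0, 1]`.
#' @param m family size, `m >= length(pvals)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1), m >= length(pvals))
  stats::p.adjust(pvals, method = "bonferroni", n = m)
}

#' Anderson-Darling normality check
#'
#' Tests a sample against the normal family with estimated mean and
#' variance (the estimated-parameters case of the Anderson-Darling test),
#' deciding at a configurable level (default 1%). Used to check that model
#' residuals are compatible with the Gaussian assumption behind the
#' SD-based residual cutoff.
#'
#' @param x numeric sample, length >= 8.
#' @param level significance level for the pass/fail decision.
#' @return list with `A2` (the statistic), `p`, `pass` (TRUE when
#'   normality is not rejected at `level`).
#' @export
anderson_darling_normality <- function(x, level = 0.01) {
  stopifnot(length(x) >= 8, all(is.finite(x)), level > 0, level < 1)
  if (stats::sd(x) == 0) {
    message("anderson_darling_normality: constant sample; degenerate failure")
    return(list(A2 = Inf, p = 0, pass = FALSE))
  }
  ht <- nortest::ad.test(x)
  list(A2 = unname(ht$statistic), p = unname(ht$p.value),
       pass = unname(ht$p.value) > level)
}

#' Best-of-factors residual per gene
#'
#' Across several factor-specific models (e.g. cohesin, CTCF, RNAPOL2),
#' selects for each gene the residual closest to zero, sign preserved —
#' the per-gene best spatial model. Ties are broken by the declared factor
#' order (first wins) and logged.
#'
#' @param residuals_by_factor named list (declared factor order) of equal
#'   gene-named residual vectors, or a genes x factors matrix.
#' @return named numeric vector of per-gene best residuals, with a
#'   `factor` attribute naming the winning factor per gene.
#' @export
spex_best <- function(residuals_by_factor) {
  if (is.list(residuals_by_factor)) {
    genes <- names(residuals_by_factor[[1]])
    for (f in residuals_by_factor) {
      if (is.null(names(f)) || !setequal(names(f), genes))
        stop("all factors must cover the same gene set")
    }
    m <- do.call(cbind, lapply(residuals_by_factor, function(f) f[genes]))
  } else {
    m <- as.matrix(residuals_by_factor)
    genes <- rownames(m)
  }
  if (any(!is.finite(m))) stop("non-finite residual")
  pick <- apply(abs(m), 1, which.min)  # first minimum wins ties
  ties <- apply(abs(m), 1, function(r) sum(r == min(r)) > 1)
  if (any(ties))
    message("spex_best: ", sum(ties),
            " tie(s) broken by declared factor order")
  best <- m[cbind(seq_len(nrow(m)), pick)]
  names(best) <- genes
  attr(best, "factor") <- colnames(m)[pick]
  best
}

#' Residual cutoff interval
#'
#' The interval `mean +/- sd_frac * SD` (sample SD) of a residual
#' distribution; with the default `sd_frac = 0.5` this is the
#' half-SD band used to call a gene "well predicted". A nonzero residual
#' mean makes the printed interval asymmetric about zero while the rule
#' stays symmetric about the mean.
#'
#' @param residuals numeric residuals, length >= 2.
#' @param sd_frac positive fraction of the SD on each side.
#' @return numeric `c(lo, hi)`.
#' @export
residual_cutoff <- function(residuals, sd_frac = 0.5) {
  stopifnot(length(residuals) >= 2, all(is.finite(residuals)))
  if (!is.numeric(sd_frac) || sd_frac <= 0)
    stop("sd_frac must be positive (a zero-width interval is degenerate)")
  s <- stats::sd(residuals)
  if (s == 0) stop("residuals have zero SD; cutoff interval degenerate")
  m <- mean(residuals)
  c(lo = m - sd_frac * s, hi = m + sd_frac * s)
}

#' Venn classification of residuals against a cutoff interval
#'
#' Classifies each gene by whether its residual falls inside `[lo, hi]` for
#' the spatial model and for the baseline: `both`, `spex_only`,
#' `baseline_only`, `neither`. The four classes partition the gene set; the
#' spatial model's within-cutoff total is `both + spex_only`.
#'
#' @param spex_res,baseline_res gene-named residual vectors over the same
#'   gene set.
#' @param interval numeric `c(lo, hi)` from [residual_cutoff()].
#' @return list with `counts` (named integer vector over the four classes
#'   plus `within_cutoff`) and `class` (per-gene factor).
#' @export
venn_classify <- function(spex_res, baseline_res, interval) {
  if (is.null(names(spex_res)) || is.null(names(baseline_res)) ||
      !setequal(names(spex_res), names(baseline_res)))
    stop("spatial and baseline residuals must cover the same gene set")
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  genes <- names(spex_res)
  b <- baseline_res[genes]
  inside <- function(x) x >= interval[1] & x <= interval[2]
  in_s <- inside(spex_res)
  in_b <- inside(b)
  cls <- ifelse(in_s & in_b, "both",
                ifelse(in_s, "spex_only",
                       ifelse(in_b, "baseline_only", "neither")))
  cls <- factor(cls, levels = c("both", "spex_only", "baseline_only",
                                "neither"))
  names(cls) <- genes
  counts <- table(cls)
  list(counts = c(both = unname(counts["both"]),
                  spex_only = unname(counts["spex_only"]),
                  baseline_only = unname(counts["baseline_only"]),
                  neither = unname(counts["neither"]),
                  within_cutoff = unname(counts["both"] +
                                           counts["spex_only"])),
       class = cls)
}

#' Compare repeated-run metrics between arms
#'
#' Given per-run metrics for several experiments, each run labelled with an
#' arm (`baseline` or `spatial`), performs Welch's t-test per experiment on
#' the chosen metric, Bonferroni-adjusts across experiments, and pools runs
#' per factor group for a group-level test. The improvement column is
#' `mean(spatial) - mean(baseline)`.
#'
#' @param runs data.frame with columns `experiment`, `group` (factor group,
#'   e.g. the mediating protein), `arm` (`"baseline"` / `"spatial"`) and the
#'   metric column.
#' @param metric name of the metric column (default `"scc"`).
#' @return list with data.frames `per_experiment` (experiment, group,
#'   mean_baseline, mean_spatial, improvement, p, p_adj) and `per_group`
#'   (group, improvement, p).
#' @export
grouped_comparison <- function(runs, metric = "scc") {
  need <- c("experiment", "group", "arm", metric)
  if (!all(need %in% names(runs)))
    stop("runs needs columns: ", paste(need, collapse = ", "))
  if (!all(runs$arm %in% c("baseline", "spatial")))
    stop("arm must be 'baseline' or 'spatial'")
  exps <- unique(runs$experiment)
  per_exp <- lapply(exps, function(e) {
    d <- runs[runs$experiment == e, ]
    a <- d[[metric]][d$arm == "spatial"]
    b <- d[[metric]][d$arm == "baseline"]
    if (length(b) < 2) stop("missing baseline arm for experiment ", e)
    if (length(a) < 2) stop("missing spatial arm for experiment ", e)
    data.frame(experiment = e, group = d$group[1],
               mean_baseline = mean(b), mean_spatial = mean(a),
               improvement = mean(a) - mean(b),
               p = welch_test(a, b)$p, stringsAsFactors = FALSE)
  })
  per_exp <- do.call(rbind, per_exp)
  per_exp$p_adj <- bonferroni(per_exp$p, m = nrow(per_exp))
  groups <- unique(per_exp$group)
  per_group <- lapply(groups, function(g) {
    d <- runs[runs$group == g, ]
    a <- d[[metric]][d$arm == "spatial"]
    b <- d[[metric]][d$arm == "baseline"]
    data.frame(group = g, improvement = mean(a) - mean(b),
               p = welch_test(a, b)$p, stringsAsFactors = FALSE)
  })
  list(per_experiment = per_exp, per_group = do.call(rbind, per_group))
}

#' Residual report: best-of-factors, cutoff and Venn analysis
#'
#' End-to-end residual analysis of a set of factor-specific spatial models
#' against a baseline on a common test gene set: per-factor residuals
#' (observed minus predicted), the per-gene best spatial residual, an
#' Anderson-Darling normality check of its distribution, the
#' `mean +/- sd_frac * SD` cutoff interval, and the Venn classification of
#' genes within the cutoff for the best spatial model versus the baseline.
#'
#' @param observed gene-named vector of observed log expression.
#' @param predicted_by_factor named list (factor order) of gene-named
#'   predicted vectors from the spatial models.
#' @param baseline_predicted gene-named predicted vector from the baseline.
#' @param sd_frac fraction of the SD for the cutoff (default 0.5).
#' @param ad_level level of the normality check.
#' @return object of class `residual_report`.
#' @export
residual_report <- function(observed, predicted_by_factor,
                            baseline_predicted, sd_frac = 0.5,
                            ad_level = 0.01) {
  genes <- names(observed)
  stopifnot(!is.null(genes))
  res_f <- lapply(predicted_by_factor, function(p) {
    if (!setequal(names(p), genes))
      stop("factor predictions must cover the observed gene set")
    observed - p[genes]
  })
  if (!setequal(names(baseline_predicted), genes))
    stop("baseline predictions must cover the observed gene set")
  res_b <- observed - baseline_predicted[genes]
  best <- spex_best(res_f)
  ad <- anderson_darling_normality(as.numeric(best), level = ad_level)
  interval <- residual_cutoff(as.numeric(best), sd_frac = sd_frac)
  venn <- venn_classify(best, res_b, interval)
  structure(list(residuals_by_factor = res_f, baseline_residuals = res_b,
                 spex_best = best, normality = ad, interval = interval,
                 sd_frac = sd_frac, venn = venn),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat("Residual report over", length(x$spex_best), "test genes\n")
  cat("  best-of-factors residuals: mean", signif(mean(x$spex_best), 4),
      "SD", signif(stats::sd(x$spex_best), 4), "\n")
  cat("  normality (Anderson-Darling): A2 =", signif(x$normality$A2, 4),
      ", p =", signif(x$normality$p, 3),
      if (x$normality$pass) "(compatible with normal)" else "(rejected)", "\n")
  cat("  cutoff interval (mean +/-", x$sd_frac, "SD): [",
      signif(x$interval[1], 4), ",", signif(x$interval[2], 4), "]\n")
  cat("  within cutoff:", x$venn$counts["within_cutoff"],
      "| both:", x$venn$counts["both"],
      "| spatial only:", x$venn$counts["spex_only"],
      "| baseline only:", x$venn$counts["baseline_only"], "\n")
  invisible(x)
}
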