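test_that("correlation and error metrics match their definitions", {
  set.seed(50)
  x <- rnorm(20)
  expect_equal(scc(x, x), 1)
  expect_equal(pcc(x, x), 1)
  expect_equal(rmse(x, x), 0)
  expect_equal(scc(sort(x), rev(sort(x))), -1)      # antitone
  expect_error(scc(rep(1, 5), x[1:5]), "constant")
  expect_error(pcc(x[1:5], rep(2, 5)), "constant")
  expect_error(scc(x, x[1:5]), "equal length")
  # Spearman = Pearson of average ranks, brute force, including ties
  for (i in 1:5) {
    a <- sample(1:10, 50, replace = TRUE)
    b <- a + sample(1:5, 50, replace = TRUE)
    expect_equal(scc(a, b), cor(rank(a), rank(b)), tolerance = 1e-12)
  }
  expect_equal(rmse(c(0, 3), c(4, 3)), sqrt(8))
})

test_that("Welch's test matches the textbook formula to 1e-10", {
  a <- c(3.1, 2.7, 4.5, 3.3, 2.9, 5.0)
  b <- c(1.2, 1.9, 0.8, 2.4)
  got <- welch_test(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  # equal variances and sizes: Satterthwaite df collapses to 2n - 2
  a2 <- c(1, 2, 3, 4)
  expect_equal(welch_test(a2, a2 + 10)$df, 6)
  expect_lt(welch_test(a2, a2 + 10)$p, 0.01)
  # null case: identical non-constant samples
  same <- welch_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # degenerate conventions
  expect_message(z <- welch_test(c(1, 1), c(1, 1)), "convention")
  expect_equal(z$p, 1)
  expect_equal(welch_test(c(1, 1), c(2, 2))$p, 0)
})

test_that("Bonferroni correction caps, preserves order and honours m", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 10), 1)
  expect_equal(bonferroni(c(0.2, 0.4)), c(0.4, 0.8))  # m = length
  expect_equal(bonferroni(0.3, m = 1), 0.3)           # identity at m = 1
  p <- c(0.001, 0.01, 0.04, 0.2)
  expect_false(is.unsorted(bonferroni(p, m = 8)))
  expect_error(bonferroni(1.2), "pvals")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m >=")
})

test_that("Anderson-Darling check accepts normal and rejects uniform draws", {
  set.seed(0)
  x_norm <- rnorm(10000)
  x_unif <- runif(10000)
  r_norm <- anderson_darling_normality(x_norm, level = 0.01)
  r_unif <- anderson_darling_normality(x_unif, level = 0.01)
  expect_true(r_norm$pass)
  expect_false(r_unif$pass)
  expect_gt(r_unif$A2, r_norm$A2)
  expect_message(r_const <- anderson_darling_normality(rep(1, 20)),
                 "degenerate")
  expect_false(r_const$pass)
})

test_that("best-of-factors residual selection keeps sign and breaks ties", {
  res <- list(cohesin = c(g1 = -0.5, g2 = 2.0, g3 = 1.0),
              ctcf = c(g1 = 2.0, g2 = -1.0, g3 = -1.0),
              rnapol2 = c(g1 = 1.0, g2 = 0.3, g3 = 2.0))
  best <- spex_best(res)
  expect_equal(as.numeric(best), c(-0.5, 0.3, 1.0))
  expect_equal(attr(best, "factor"),
               c("cohesin", "rnapol2", "cohesin"))  # tie: declared order wins
  expect_message(spex_best(list(a = c(g = 1), b = c(g = -1))), "tie")
  expect_equal(as.numeric(spex_best(list(a = c(g = 1), b = c(g = -1)))), 1)
  # single factor: identity
  expect_equal(as.numeric(spex_best(res["ctcf"])), unname(res$ctcf))
  expect_error(spex_best(list(a = c(g1 = 1), b = c(g2 = 1))),
               "same gene set")
})

test_that("residual cutoff is mean +/- frac * sample SD", {
  r <- c(-2, 0, 2)                     # mean 0, SD 2
  expect_equal(residual_cutoff(r, 0.5), c(lo = -1, hi = 1))
  set.seed(8)
  x <- rnorm(500, 3, 2)
  expect_equal(unname(residual_cutoff(x, 0.5)),
               c(mean(x) - 0.5 * sd(x), mean(x) + 0.5 * sd(x)))
  expect_error(residual_cutoff(r, 0), "positive")
  expect_error(residual_cutoff(c(1, 1, 1)), "zero SD")
})

test_that("Venn classification partitions genes and matches set algebra", {
  s <- c(a = 0.1, b = 5, c = 0, d = -3)
  b <- c(a = 5, b = 0.2, c = 0, d = 9)
  v <- venn_classify(s, b, c(-1, 1))
  expect_equal(unname(v$counts[c("both", "spex_only", "baseline_only",
                                 "neither")]), c(1L, 1L, 1L, 1L))
  expect_equal(as.character(v$class["a"]), "spex_only")
  expect_equal(as.character(v$class["c"]), "both")
  # 500-gene random fixture against brute-force set operations
  set.seed(91)
  genes <- sprintf("g%03d", 1:500)
  rs <- setNames(rnorm(500, 0.3, 2), genes)
  rb <- setNames(rnorm(500, 0.5, 3), genes)
  iv <- residual_cutoff(rs, 0.5)
  v <- venn_classify(rs, rb, iv)
  in_s <- names(rs)[rs >= iv[1] & rs <= iv[2]]
  in_b <- names(rb)[rb >= iv[1] & rb <= iv[2]]
  expect_equal(unname(v$counts["both"]), length(intersect(in_s, in_b)))
  expect_equal(unname(v$counts["spex_only"]), length(setdiff(in_s, in_b)))
  expect_equal(unname(v$counts["baseline_only"]), length(setdiff(in_b, in_s)))
  expect_equal(unname(v$counts["within_cutoff"]), length(in_s))
  expect_equal(sum(v$counts[c("both", "spex_only", "baseline_only",
                              "neither")]), 500L)
  expect_error(venn_classify(rs[1:10], rb[11:20], iv), "same gene set")
})

test_that("grouped comparisons test arms per experiment and per group", {
  mk <- function(experiment, group, arm, values)
    data.frame(experiment = experiment, group = group, arm = arm,
               scc = values, stringsAsFactors = FALSE)
  # identical arms: adjusted p stays 1
  same <- rbind(mk("e1", "ctcf", "baseline", c(0.8, 0.81, 0.79)),
                mk("e1", "ctcf", "spatial", c(0.8, 0.81, 0.79)))
  r <- grouped_comparison(same)
  expect_equal(r$per_experiment$p_adj, 1)
  expect_equal(r$per_experiment$improvement, 0)
  # planted mean shift 0.02, SD 0.005, n = 100 per arm: tiny adjusted p
  set.seed(0)
  shift <- rbind(mk("e1", "ctcf", "baseline", rnorm(100, 0.80, 0.005)),
                 mk("e1", "ctcf", "spatial", rnorm(100, 0.82, 0.005)),
                 mk("e2", "cohesin", "baseline", rnorm(100, 0.80, 0.005)),
                 mk("e2", "cohesin", "spatial", rnorm(100, 0.82, 0.005)))
  r <- grouped_comparison(shift)
  expect_true(all(r$per_experiment$p_adj < 1e-6))
  expect_true(all(r$per_group$p < 1e-6))
  # improvement equals the difference of manual means
  d <- shift[shift$experiment == "e1", ]
  expect_equal(r$per_experiment$improvement[1],
               mean(d$scc[d$arm == "spatial"]) -
                 mean(d$scc[d$arm == "baseline"]))
  expect_error(grouped_comparison(mk("e1", "g", "spatial", c(1, 2))),
               "missing baseline")
})

test_that("null-calibrated comparisons reject at about the nominal level", {
  set.seed(123)
  n_reject <- 0L
  for (i in 1:200) {
    p <- welch_test(rnorm(10), rnorm(10))$p
    if (p < 0.05) n_reject <- n_reject + 1L
  }
  # expected 10 rejections; allow ~3 binomial SDs
  expect_lte(n_reject, 20L)
})

test_that("the residual report assembles cutoff, normality and Venn counts", {
  set.seed(14)
  genes <- sprintf("g%03d", 1:300)
  obs <- setNames(rnorm(300), genes)
  preds <- list(cohesin = obs + rnorm(300, 0, 1.0),
                ctcf = obs + rnorm(300, 0, 1.2),
                rnapol2 = obs + rnorm(300, 0, 0.8))
  base <- obs + rnorm(300, 0, 2)
  rep_ <- residual_report(obs, preds, base)
  expect_s3_class(rep_, "residual_report")
  expect_equal(rep_$baseline_residuals, obs - base)
  # the best-of-factors residual is never larger in magnitude than any factor
  for (f in names(preds))
    expect_true(all(abs(rep_$spex_best) <=
                      abs(rep_$residuals_by_factor[[f]]) + 1e-12))
  expect_equal(unname(rep_$interval),
               unname(residual_cutoff(as.numeric(rep_$spex_best))))
  expect_output(print(rep_), "within cutoff")
})
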