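random_gene_table <- function(n, chroms) {
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             tss = sample.int(1e6, n), strand = "+",
             stringsAsFactors = FALSE)
}

test_that("chromosome holdout splits partition the gene set", {
  genes <- data.frame(gene_id = c("a", "b", "c"),
                      chrom = c("chr1", "chr8", "chrX"),
                      tss = c(1L, 2L, 3L), strand = "+",
                      stringsAsFactors = FALSE)
  sp <- chromosome_split(genes)
  expect_equal(sp$train_ids, "a")
  expect_equal(sp$test_ids, "b")
  expect_equal(sp$excluded_ids, "c")
  expect_error(chromosome_split(genes[1, ]), "no genes on test chromosome")
  expect_error(split_spec(test_chrom = "chrX"), "must not be in excluded")

  set.seed(31)
  big <- random_gene_table(1000, c(paste0("chr", 1:12), "chrX", "chrY"))
  sp <- chromosome_split(big)
  expect_equal(length(sp$train_ids) + length(sp$test_ids) +
                 length(sp$excluded_ids), 1000L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_length(intersect(sp$train_ids, sp$excluded_ids), 0)
  expect_true(all(big$chrom[big$gene_id %in% sp$test_ids] == "chr8"))
})

test_that("the boosted-tree fit is sane, deterministic and serializable", {
  set.seed(77)
  X <- matrix(rnorm(200 * 30), 200, 30,
              dimnames = list(sprintf("g%03d", 1:200), paste0("f", 1:30)))
  # constant target: a degenerate fit predicts the constant
  m0 <- fit_expression_model(X, rep(2.5, 200), model_config(n_rounds = 20))
  expect_equal(unname(predict(m0, X)), rep(2.5, 200), tolerance = 1e-6)

  # noiseless linear function of one column is learned almost perfectly
  y <- 3 * X[, 7]
  m1 <- fit_expression_model(X, y, model_config())
  expect_gt(scc(predict(m1, X), y), 0.99)

  # determinism: same data and seed give identical predictions
  m2 <- fit_expression_model(X, y, model_config())
  expect_identical(predict(m1, X), predict(m2, X))
  m3 <- fit_expression_model(X, y, model_config(seed = 9))
  expect_false(identical(predict(m1, X), predict(m3, X)))

  # save / load round trip preserves predictions exactly
  f <- withr::local_tempfile(fileext = ".ubj")
  save_expression_model(m1, f)
  m1b <- load_expression_model(f)
  expect_equal(predict(m1b, X), predict(m1, X))
  expect_equal(m1b$feature_names, m1$feature_names)

  # permuting gene rows permutes predictions identically
  perm <- sample(200)
  expect_equal(predict(m1, X[perm, ]), predict(m1, X)[perm])
  # empty input, layout mismatch, non-finite features
  expect_length(predict(m1, X[0, , drop = FALSE]), 0)
  Xbad <- X
  colnames(Xbad) <- rev(colnames(X))
  expect_error(predict(m1, Xbad), "layout mismatch")
  Xna <- X
  Xna[3, 4] <- NA
  expect_error(fit_expression_model(Xna, y), "g003.*f4")
})

test_that("the linear-booster baseline configuration also fits", {
  set.seed(17)
  X <- matrix(rnorm(150 * 10), 150, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- X %*% rnorm(10) + rnorm(150, 0, 0.01)
  m <- fit_expression_model(X, as.numeric(y),
                            model_config(booster = "linear", n_rounds = 100))
  expect_gt(pcc(predict(m, X), as.numeric(y)), 0.95)
})

test_that("repeated runs record seeds and reproduce exactly", {
  set.seed(3)
  X <- matrix(rnorm(120 * 15), 120, 15,
              dimnames = list(NULL, paste0("f", 1:15)))
  y <- X[, 2] + rnorm(120, 0, 0.3)
  cfg <- model_config(n_rounds = 30)
  r1 <- repeated_runs(X[1:80, ], y[1:80], X[81:120, ], y[81:120], cfg,
                      n_runs = 5, base_seed = 10)
  expect_equal(nrow(r1), 5L)
  expect_equal(r1$seed, 10:14)
  expect_true(all(abs(r1$scc) <= 1) && all(r1$rmse >= 0))
  # reproducibility of the whole table
  r2 <- repeated_runs(X[1:80, ], y[1:80], X[81:120, ], y[81:120], cfg,
                      n_runs = 5, base_seed = 10)
  expect_identical(r1, r2)
  # n_runs = 1 reduces to a single fit with the base seed
  r3 <- repeated_runs(X[1:80, ], y[1:80], X[81:120, ], y[81:120], cfg,
                      n_runs = 1, base_seed = 10)
  expect_equal(r3[, c("scc", "pcc", "rmse")], r1[1, c("scc", "pcc", "rmse")])
})

test_that("no test gene's target can influence training (canary)", {
  fx <- small_dataset()
  expr2 <- fx$ds$expression
  test_gene <- chromosome_split(fx$ds$genes)$test_ids[1]
  expr2[test_gene, 1] <- expr2[test_gene, 1] * 100 + 50
  cfg <- model_config(n_rounds = 30)
  fit1 <- spex(fx$archive, fx$ds$expression, config = cfg)
  fit2 <- spex(fx$archive, expr2, config = cfg)
  # training output unchanged: identical predictions for every test gene
  expect_identical(fit1$predicted, fit2$predicted)
  # only the perturbed gene's observed value moved
  expect_equal(fit1$observed[setdiff(names(fit1$observed), test_gene)],
               fit2$observed[setdiff(names(fit2$observed), test_gene)])
})

test_that("the spex front-end returns a coherent fitted-model object", {
  fx <- small_dataset()
  fit <- spex(fx$archive, fx$ds$expression, config = model_config(n_rounds = 40))
  expect_s3_class(fit, "spex_fit")
  expect_named(fit$metrics, c("scc", "pcc", "rmse"))
  expect_equal(residuals(fit), fit$observed - fit$predicted)
  expect_equal(fitted(fit), fit$predicted)
  expect_output(print(fit), "spatial arm")
  expect_output(print(summary(fit)), "test SCC")
  # predict on a fresh archive reproduces the stored test predictions
  p <- predict(fit, fx$archive, gene_ids = names(fit$predicted))
  expect_equal(p, fit$predicted)
  # baseline arm drops the spatial columns
  fit_b <- spex(fx$archive, fx$ds$expression, spatial = FALSE,
                config = model_config(n_rounds = 40))
  expect_equal(length(fit_b$model$feature_names), 20 * 20)
})
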