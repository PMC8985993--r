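test_that("the production configuration carries the reference defaults", {
  cfg <- gbt_config()
  expect_equal(cfg$n_estimators, 40000L)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$max_depth, 6L)
  expect_equal(cfg$subsample, 0.7)
  expect_equal(cfg$min_samples_split, 2L)
  expect_equal(cfg$max_features, "sqrt")
  expect_equal(cfg$repetitions, 10L)
  red <- gbt_config_reduced()
  expect_equal(red$n_estimators, 500L)
  expect_equal(red$learning_rate, 0.05)
  expect_equal(red$max_depth, 6L)
})

test_that("constant labels give constant predictions", {
  x <- with_seed(1, matrix(rnorm(50 * 10), 50))
  fit <- dc_gbt(x, rep(4.2, 50), gbt_config_reduced(n_estimators = 50L),
                seed = 1)
  pred <- predict(fit, x)
  expect_true(all(abs(pred - 4.2) < 1e-3))
  expect_equal(length(unique(round(pred, 6))), 1L)
})

test_that("fits are deterministic given the seed", {
  x <- with_seed(2, matrix(rnorm(60 * 20), 60))
  y <- with_seed(3, rnorm(60))
  f1 <- dc_gbt(x, y, gbt_config_reduced(n_estimators = 100L), seed = 11)
  f2 <- dc_gbt(x, y, gbt_config_reduced(n_estimators = 100L), seed = 11)
  expect_identical(predict(f1, x), predict(f2, x))
  expect_equal(residuals(f1), y - f1$fitted)
})

test_that("a planted linear signal in one of 100 columns is recovered", {
  n <- 200
  x <- with_seed(5, matrix(rnorm(n * 100), n))
  y <- 2 * x[, 17] + with_seed(6, rnorm(n, sd = 0.2))
  tr <- 1:150; te <- 151:200
  fit <- dc_gbt(x[tr, ], y[tr], gbt_config_reduced(), seed = 5)
  ev <- evaluate_scoring(predict(fit, x[te, ]), y[te])
  expect_gt(ev$pcc, 0.8)
})

test_that("fit rejects malformed inputs", {
  x <- matrix(1:20 + 0, 10)
  expect_error(dc_gbt(x, 1:9), "length")
  expect_error(dc_gbt(x[1, , drop = FALSE], 1), "two")
  xx <- x; xx[3, 1] <- NA
  expect_error(dc_gbt(xx, 1:10), "finite")
  expect_error(dc_gbt(x, c(1:9, Inf)), "finite")
})

test_that("scoring metrics behave and flag degenerate predictions", {
  y <- c(1, 2, 3, 4.5)
  expect_equal(evaluate_scoring(y, y), list(pcc = 1, rmse = 0,
                                            degenerate = FALSE))
  ev <- evaluate_scoring(-y, y)
  expect_equal(ev$pcc, -1)
  expect_gt(ev$rmse, 0)
  dg <- evaluate_scoring(rep(2, 4), y)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$pcc))
  # PCC is invariant under positive affine maps of predictions; RMSE not
  p <- c(0.9, 2.2, 2.8, 4.6)
  expect_equal(evaluate_scoring(3 * p + 1, y)$pcc,
               evaluate_scoring(p, y)$pcc)
  expect_false(isTRUE(all.equal(evaluate_scoring(3 * p + 1, y)$rmse,
                                evaluate_scoring(p, y)$rmse)))
})

test_that("scoring_power reports per-repetition values and their medians", {
  x <- with_seed(8, matrix(rnorm(80 * 30), 80))
  y <- x[, 3] + with_seed(9, rnorm(80, sd = 0.1))
  res <- scoring_power(x[1:60, ], y[1:60], x[61:80, ], y[61:80],
                       gbt_config_reduced(n_estimators = 60L,
                                          repetitions = 4L), seed = 2)
  expect_equal(nrow(res$per_repetition), 4L)
  expect_equal(res$pcc, stats::median(res$per_repetition$pcc))
  expect_equal(res$rmse, stats::median(res$per_repetition$rmse))
})

test_that("enrichment factors count binders in the expanded top set", {
  # 100 molecules, 10 binders, 5 of them in the top 10 ranked
  scores <- 100:1
  binders <- rep(FALSE, 100)
  binders[c(1, 3, 5, 7, 9, 60, 70, 80, 90, 99)] <- TRUE
  expect_equal(enrichment_factor(scores, binders, 10), 5)
  # all binders ranked last
  b2 <- c(rep(FALSE, 90), rep(TRUE, 10))
  expect_equal(enrichment_factor(scores, b2, 10), 0)
  expect_error(enrichment_factor(scores, rep(FALSE, 100), 10), "binder")
  expect_error(enrichment_factor(scores, binders, 0))
})

test_that("a random ranking has enrichment close to one on average", {
  efs <- vapply(1:300, function(s) {
    scores <- with_seed(2000 + s, runif(100))
    binders <- rep(c(TRUE, FALSE), c(10, 90))
    enrichment_factor(scores, binders, 20)
  }, numeric(1))
  # mean of 300 x (Binomial(10, .2)/2): se ~ 0.035, allow 4 sigma
  expect_lt(abs(mean(efs) - 1), 0.15)
})

test_that("tied top candidates in the 195/1% screen report 66.6", {
  scores <- c(rep(9.99, 3), round(with_seed(12, runif(192, 1, 9)), 2))
  binders <- c(TRUE, TRUE, FALSE, rep(c(TRUE, FALSE), c(1, 191)))
  expect_equal(enrichment_factor(scores, binders, 1), 66.6)
  # without tie inflation the plain formula applies
  scores2 <- c(10, 9.9, round(with_seed(13, runif(193, 1, 9)), 2))
  expect_equal(enrichment_factor(scores2, binders, 1), 2 / (3 * 0.01))
})

test_that("docking success demands strict sub-2-Angstrom best poses", {
  expect_true(docking_success(c(1, 5, 3), c(4, 1.5, 3)))
  expect_false(docking_success(c(1, 5, 3), c(4, 2.0, 3)))
  # score tie resolves to the lowest pose index
  expect_true(docking_success(c(5, 5), c(1.0, 4.0)))
  expect_false(docking_success(c(5, 5), c(4.0, 1.0)))
})

test_that("success aggregation applies the minimum-repetition rule", {
  expect_true(aggregate_success(rep(c(TRUE, FALSE), c(3, 7)), 3))
  expect_false(aggregate_success(rep(c(TRUE, FALSE), c(2, 8)), 3))
  expect_true(aggregate_success(rep(TRUE, 10), 3))
  expect_true(aggregate_success(rep(c(TRUE, FALSE), c(2, 8)), 2))
})

test_that("screening labels convert, clamp decoys, and drop negatives", {
  out <- prepare_screening_labels(c(-10, -12.2683, 1.0),
                                  binder_energies = c(6.0, 7.5))
  expect_equal(out$energy[1], 6.0)           # 7.335 clamps to the bound
  expect_equal(out$energy[2], 6.0)           # 9.0 clamps too
  expect_equal(out$energy[3], -0.7335)
  expect_equal(out$kept, c(TRUE, TRUE, FALSE))
  # non-decoys are never clamped
  out2 <- prepare_screening_labels(c(-10), c(6.0), is_decoy = FALSE)
  expect_equal(out2$energy, 7.335)
  expect_error(prepare_screening_labels(c(-1), numeric(0)), "empty")
  expect_equal(round_screening_energies(c(7.3351, 6.666)), c(7.34, 6.67))
})
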