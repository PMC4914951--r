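test_that("cumulative Q2Y follows the product formula", {
  expect_equal(cumulative_q2y(c(0.5, 0.2)), 0.6)
  expect_equal(cumulative_q2y(0.37), 0.37)  # empty-product case
  q <- c(0.4, -0.1, 0.05)
  expect_equal(cumulative_q2y(q), 1 - (1 - 0.4) * (1 + 0.1) * (1 - 0.05))
})

test_that("single-component weights are proportional to X_scaled' y", {
  d <- simulate_planted(n_per_class = 10, p = 12, n_informative = 2, d = 2,
                        seed = 3)
  fit <- fit_plsda(d, "class", seed = 1)
  e <- fit$engine
  X <- as.matrix(d[sprintf("f%04d", 1:12)])
  Xs <- scale(X)
  y <- ifelse(d$class == e$positive, 0.5, -0.5)
  ref <- drop(crossprod(Xs, y - mean(y)))
  w1 <- e$weights[, 1]
  cosine <- sum(w1 * ref) / sqrt(sum(w1^2) * sum(ref^2))
  expect_equal(cosine, 1, tolerance = 1e-8)
})

test_that("VIP is normalised, symmetric under symmetry, and discriminating", {
  # p = 1: normalisation forces VIP = 1
  d1 <- separable_toy(8)[c("class", "f1")]
  expect_equal(unname(vip(fit_plsda(d1, "class"))), 1)
  # sum of squares = p
  d <- simulate_planted(n_per_class = 10, p = 15, n_informative = 3, d = 1.5,
                        seed = 9)
  v <- vip(fit_plsda(d, "class"))
  expect_equal(sum(v^2), 15, tolerance = 1e-8)
  # orthogonal toy: informative feature above 1, noise feature below
  toy <- separable_toy(15, seed = 4)
  v2 <- vip(fit_plsda(toy, "class"))
  expect_gt(v2[["f1"]], 1)
  expect_lt(v2[["f2"]], 1)
})

test_that("perfectly separated toy predicts its training set exactly", {
  toy <- separable_toy(10, seed = 2)
  fit <- fit_plsda(toy, "class")
  expect_true(fit$engine$informative)
  pred <- predict(fit, toy)
  expect_identical(pred$predicted, toy$class)
})

test_that("pure-noise response yields a non-informative model (n < 100)", {
  # with n = 60 < 100 the first component must clear Q2Y >= 0.05; on noise
  # this fails in most seeds
  flags <- vapply(1:10, function(s) {
    d <- simulate_planted(n_per_class = 30, p = 20, d = 0, seed = 100 + s)
    fit_plsda(d, "class", seed = s)$engine$informative
  }, logical(1))
  expect_lt(mean(flags), 0.5)
})

test_that("non-informative models predict the training majority level", {
  d <- simulate_planted(n_per_class = 10, p = 5, d = 0, seed = 42)
  d$class <- c(rep("case", 6), rep("control", 14))
  fit <- fit_plsda(d, "class", seed = 1)
  if (!fit$engine$informative) {
    pred <- predict(fit, d)
    expect_true(all(pred$predicted == "control"))
    expect_true(all(is.na(pred$y_hat)))
  }
  # direct contract check on the engine's majority field
  expect_identical(fit$engine$majority, "control")
})

test_that("cumulative Q2Y is bounded by 1 and centred below 0 on noise", {
  q2 <- vapply(1:12, function(s) {
    d <- simulate_planted(n_per_class = 15, p = 10, d = 0, seed = 200 + s)
    fit_plsda(d, "class", seed = s)$engine$q2y_cum
  }, numeric(1))
  expect_true(all(q2 <= 1))
  expect_lte(mean(q2), 0)
})

test_that("component admission respects the R2Y/Q2Y thresholds", {
  toy <- separable_toy(20, seed = 6)
  e <- fit_plsda(toy, "class", seed = 3)$engine
  expect_gte(e$r_admitted, 1)
  expect_true(all(e$r2y >= 0.01))
  expect_true(all(e$q2y[seq_len(e$r_admitted)] >= 0.05))  # n = 40 < 100
  expect_lte(e$r, min(10, nrow(toy) - 1, 2))
})

test_that("the engine agrees with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  d <- simulate_planted(n_per_class = 12, p = 8, n_informative = 2, d = 1.5,
                        seed = 13)
  X <- as.matrix(d[sprintf("f%04d", 1:8)])
  fit <- fit_plsda(d, "class", seed = 1)
  ref <- mixOmics::plsda(X, factor(d$class), ncomp = 1)
  w_ref <- ref$loadings$X[, 1]
  w_own <- fit$engine$weights[, 1]
  cosine <- abs(sum(w_ref * w_own) / sqrt(sum(w_ref^2) * sum(w_own^2)))
  expect_equal(cosine, 1, tolerance = 1e-6)
})

test_that("zero-variance features are scaled with a guarded divisor", {
  toy <- separable_toy(8, seed = 8)
  toy$f3 <- 2.5  # constant column
  fit <- fit_plsda(toy, "class")
  expect_true(fit$engine$scaling$flagged[["f3"]])
  expect_equal(fit$engine$scaling$sd[["f3"]], 1)
  expect_identical(predict(fit, toy)$predicted, toy$class)
})
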