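test_that("Lustgarten similarity matches hand arithmetic and conventions", {
  expect_equal(lustgarten_similarity(c("f1", "f2"), c("f1", "f2"), 10), 0.8)
  expect_equal(lustgarten_similarity(c("f1", "f2"), c("f3", "f4"), 10), -0.2)
  expect_equal(lustgarten_similarity(character(0), c("f1"), 10), 0)
  expect_equal(lustgarten_similarity(letters[1:6], letters[1:6], 6), 0)  # degenerate denominator
  expect_error(lustgarten_similarity("f1", "f1", 0), "positive")
})

test_that("Lustgarten similarity equals exhaustive enumeration on a 6-universe", {
  universe <- paste0("f", 1:6)
  all_subsets <- unlist(lapply(0:6, function(k) {
    combn(universe, k, simplify = FALSE)
  }), recursive = FALSE)
  for (a in all_subsets) {
    for (b in all_subsets) {
      expect_equal(lustgarten_similarity(a, b, 6),
                   oracle_lustgarten(a, b, universe),
                   tolerance = 1e-12)
      expect_equal(lustgarten_similarity(a, b, 6),
                   lustgarten_similarity(b, a, 6))  # symmetry
    }
  }
})

test_that("chance-level selections have mean similarity near zero", {
  universe <- paste0("f", 1:40)
  sims <- withr::with_seed(8, vapply(1:400, function(i) {
    lustgarten_similarity(sample(universe, 5), sample(universe, 12), 40)
  }, numeric(1)))
  expect_lt(abs(mean(sims)), 0.05)
})

test_that("performance is the harmonic mean, bounded by the arithmetic mean", {
  expect_equal(selection_performance(0.9, 0.5), 2 * 0.9 * 0.5 / 1.4)
  expect_equal(selection_performance(0.7, 0.7), 0.7)
  expect_equal(selection_performance(0, 0), 0)
  for (i in 1:50) {
    ab <- withr::with_seed(i, runif(2))
    h <- selection_performance(ab[1], ab[2])
    expect_lte(h, sqrt(prod(ab)) + 1e-12)        # <= geometric
    expect_lte(sqrt(prod(ab)), mean(ab) + 1e-12) # <= arithmetic
  }
})

test_that("stability of a constant selector follows the similarity arithmetic", {
  d <- simulate_planted(n_per_class = 10, p = 10, d = 0, seed = 55)
  const_selector <- function(data, class, seed) {
    list(features = c("f0001", "f0002"), accuracy = 0.8)
  }
  st <- signature_stability(d, "class", const_selector, seed = 1)
  expect_equal(st$stability, 0.8)  # (2 - 0.4) / 2 for every one of the 45 pairs
  expect_equal(st$accuracy, 0.8)
  expect_equal(st$performance, 0.8)  # acc == stab -> harmonic mean identity
  expect_equal(nrow(tidy(st)), 45)
})

test_that("stability subsets are stratified 90% complements", {
  d <- simulate_planted(n_per_class = 15, p = 5, d = 0, seed = 66)
  seen <- list()
  probe <- function(data, class, seed) {
    seen[[length(seen) + 1]] <<- data
    list(features = "f0001", accuracy = 0.5)
  }
  invisible(signature_stability(d, "class", probe, seed = 2))
  sizes <- vapply(seen[1:10], nrow, numeric(1))
  expect_equal(mean(sizes), 27)        # 90% of 30 on average
  expect_true(all(sizes >= 26 & sizes <= 28))
  for (s in seen[1:10]) {
    expect_true(all(table(s$.class) >= 12))  # both classes retained
  }
})

test_that("Q2Y permutation test separates signal from noise", {
  toy <- separable_toy(15, seed = 12)
  res <- q2y_permutation_test(toy, "class", n_perm = 50, seed = 3)
  expect_equal(res$p_value, 0)
  expect_gt(res$q2y_obs, 0.5)
  expect_length(res$q2y_perm, 50)
  # p-value does not depend on which class is labelled positive
  res_b <- q2y_permutation_test(toy, "class", positive_level = "a",
                                n_perm = 50, seed = 3)
  expect_equal(res_b$p_value, res$p_value)
  expect_equal(res_b$q2y_obs, res$q2y_obs)
})

test_that("Q2Y permutation p-values are well-calibrated under the null", {
  pvals <- vapply(1:6, function(s) {
    d <- simulate_planted(n_per_class = 12, p = 8, d = 0, seed = 400 + s)
    q2y_permutation_test(d, "class", n_perm = 40, seed = s)$p_value
  }, numeric(1))
  expect_true(all(pvals >= 0 & pvals <= 1))
  expect_gt(mean(pvals), 0.15)  # nowhere near uniformly significant
})
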