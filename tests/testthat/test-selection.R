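test_that("bootstrap splits are stratified, seeded, and out-of-bag is valid", {
  labels <- rep(c("a", "b"), c(12, 8))
  sp1 <- bootstrap_splits(labels, boot = 20, seed = 4)
  sp2 <- bootstrap_splits(labels, boot = 20, seed = 4)
  expect_identical(sp1, sp2)
  for (s in sp1) {
    expect_length(s$train, 20)
    expect_identical(sort(unique(labels[s$train])), c("a", "b"))
    # class balance preserved in the training multiset
    expect_equal(sum(labels[s$train] == "a"), 12)
    expect_gt(length(s$test), 0)
    expect_identical(sort(unique(labels[s$test])), c("a", "b"))
    expect_length(intersect(s$train, s$test), 0)
  }
})

test_that("mean out-of-bag fraction approaches 1/e for large n", {
  labels <- rep(c("a", "b"), each = 100)
  sp <- bootstrap_splits(labels, boot = 60, seed = 7)
  oob_frac <- mean(vapply(sp, function(s) length(s$test) / 200, numeric(1)))
  # a sample escapes its class's 100 draws with probability (1 - 1/100)^100
  expect_equal(oob_frac, (1 - 1 / 100)^100, tolerance = 0.03 / 0.36)
})

test_that("balanced accuracy equals the mean of sensitivity and specificity", {
  expect_equal(balanced_accuracy(c("a", "b", "a", "b"),
                                 c("a", "b", "a", "b"), "b"), 1)
  # constant prediction scores 0.5 whatever the imbalance
  truth <- rep(c("a", "b"), c(9, 1))
  expect_equal(balanced_accuracy(truth, rep("a", 10), "b"), 0.5)
  # sens 0.8, spec 0.6 -> 0.7
  truth <- rep(c("pos", "neg"), c(5, 5))
  pred <- c("pos", "pos", "pos", "pos", "neg", "neg", "neg", "neg", "pos", "pos")
  expect_equal(balanced_accuracy(truth, pred, "pos"), 0.7)
  expect_error(balanced_accuracy(rep("a", 4), rep("a", 4), "a"),
               "single class")
})

test_that("median rank aggregation matches hand-computed examples", {
  m <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3))
  expect_identical(unname(aggregate_ranks(m)), c(1L, 2L, 3L))
  expect_identical(unname(aggregate_ranks(rbind(c(2, 1, 3)))), c(2L, 1L, 3L))
  # tied medians and tied means resolve by feature index
  expect_identical(unname(aggregate_ranks(rbind(c(1, 2), c(2, 1)))), c(1L, 2L))
  expect_error(aggregate_ranks(rbind(c(1, 1, 2))), "permutation")
})

test_that("subset permutation preserves the multiset and spares other columns", {
  X <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("f", 1:6)))
  Xp <- permute_subset(X, c("f2", "f5"), seed = 3)
  expect_equal(sort(Xp[, "f2"]), sort(X[, "f2"]))
  expect_equal(sort(Xp[, "f5"]), sort(X[, "f5"]))
  expect_identical(Xp[, c("f1", "f3", "f4", "f6")],
                   X[, c("f1", "f3", "f4", "f6")])
  expect_identical(permute_subset(X, character(0)), X)
  # single-row test set: only one arrangement exists
  X1 <- X[1, , drop = FALSE]
  expect_identical(permute_subset(X1, colnames(X1), seed = 1), X1)
  expect_error(permute_subset(X, "f9"), "f9")
})

test_that("the significance rule reads non-exceedance strictly against alpha", {
  ref <- rep(0.8, 50)
  perm2 <- c(rep(0.8, 2), rep(0.5, 48))   # exactly 2 non-drops -> 0.04
  perm3 <- c(rep(0.8, 3), rep(0.5, 47))   # exactly 3 non-drops -> 0.06
  v2 <- subset_verdict(perm2, ref, alpha = 0.05)
  v3 <- subset_verdict(perm3, ref, alpha = 0.05)
  expect_true(v2$significant)
  expect_equal(v2$proportion, 0.04)
  expect_false(v3$significant)
  expect_equal(v3$proportion, 0.06)
  # no-change and all-drop boundaries are forced
  expect_false(subset_verdict(ref, ref, 0.05)$significant)
  expect_true(subset_verdict(rep(0.4, 50), ref, 0.05)$significant)
})

test_that("half-interval search equals the exhaustive scan on monotone oracles", {
  for (p in c(1, 2, 5, 8, 13)) {
    for (t in 0:p) {
      verdicts <- c(rep(TRUE, t), rep(FALSE, p - t))
      visited <- integer(0)
      res <- half_interval_search(p, function(f) {
        visited <<- c(visited, f)
        list(significant = verdicts[f], proportion = ifelse(verdicts[f], 0, 1))
      })
      expect_identical(res$f_ns, oracle_search_boundary(verdicts))
      expect_identical(res$significant_ranks, seq_len(t))
      expect_identical(res$trace$candidate_rank, visited)
      expect_lte(nrow(res$trace), ceiling(log2(p + 1)) + 2)
    }
  }
})

test_that("the search visits full set, then halves, as in the 100/50/75 pattern", {
  # p = 16: all features significant, top half not, top quarter not
  verdicts <- function(f) f <= 4
  res <- half_interval_search(16, function(f) {
    list(significant = verdicts(f), proportion = 0)
  })
  expect_identical(res$trace$candidate_rank[1:3], c(1L, 9L, 5L))
  expect_identical(res$trace$subset_size[1:3], c(16L, 8L, 12L))
  expect_identical(res$f_ns, 5L)
})

test_that("permuting an irrelevant subset leaves significance undetected", {
  d <- separable_toy(12, seed = 5)
  d$f3 <- withr::with_seed(6, rnorm(24))
  fits <- bootstrap_fits(d, "class", method = "plsda", boot = 20, seed = 2)
  # noise-only subset: accuracy cannot drop much -> not significant
  noise <- subset_significance(fits, c("f2", "f3"), alpha = 0.05, seed = 1)
  expect_false(noise$significant)
  # subset containing the separating feature: accuracy collapses
  signal <- subset_significance(fits, c("f1", "f2", "f3"), alpha = 0.05, seed = 1)
  expect_true(signal$significant)
  expect_lt(signal$proportion, noise$proportion)
})

test_that("models are fitted once per round and reused across candidates", {
  d <- separable_toy(10, seed = 9)
  fits <- bootstrap_fits(d, "class", method = "svm", boot = 10, seed = 3)
  before <- lapply(fits$models, function(m) m$weights)
  invisible(subset_significance(fits, "f1", seed = 1))
  invisible(subset_significance(fits, c("f1", "f2"), seed = 2))
  expect_identical(lapply(fits$models, function(m) m$weights), before)
  # train matrix untouched by permutation evaluations
  expect_identical(fits$x$X, as_sig_data(d, "class")$X)
})

test_that("a selection round registers a dominant feature and halves on noise", {
  toy <- separable_toy(12, seed = 10)
  rs <- selection_round(toy, "class", method = "plsda", boot = 20, seed = 8)
  expect_true(rs$registered)
  expect_true("f1" %in% rs$features)
  null_d <- simulate_planted(n_per_class = 10, p = 12, d = 0, seed = 77)
  rs0 <- selection_round(null_d, "class", method = "plsda", boot = 20, seed = 8)
  if (!rs0$registered) {
    expect_length(rs0$features, 6)  # ceiling(12 / 2) most-important kept
  }
})

test_that("iterated selection converges and tiers partition the features", {
  d <- simulate_planted(n_per_class = 15, p = 20, n_informative = 1, d = 3,
                        seed = 14)
  sel <- select_signature(d, "class", methods = c("plsda", "svm"), boot = 20,
                          seed = 14)
  for (r in sel$results) {
    expect_true(r$converged)
    tiers <- r$tiers
    expect_setequal(names(tiers), sprintf("f%04d", 1:20))
    expect_true(all(tiers[r$signature] == "S"))
    expect_true(all(stats::na.omit(unique(tiers)) %in% c("S", "A", "B", "C", "D", "E")))
    # S features never carry another tier; all features are binned
    expect_false(anyNA(tiers))
  }
  expect_true("f0001" %in% unique(unlist(signatures(sel))))
  td <- tidy(sel)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 40)  # 20 features x 2 methods
  g <- glance(sel)
  expect_equal(g$union_size >= 1, TRUE)
})

test_that("a single non-significant feature yields an empty signature", {
  d <- simulate_planted(n_per_class = 10, p = 1, d = 0, seed = 31)
  sel <- select_signature(d, "class", methods = "plsda", boot = 20, seed = 31)
  r <- sel$results$plsda
  expect_true(r$converged)
  expect_length(r$signature, 0)
  expect_identical(unname(r$tiers["f0001"]), "A")
  expect_true(is.na(sel$accuracy$balanced_accuracy[sel$accuracy$model == "S"]))
})

test_that("the whole selection is bit-identical under a fixed seed", {
  d <- simulate_planted(n_per_class = 10, p = 10, n_informative = 1, d = 2.5,
                        seed = 19)
  s1 <- select_signature(d, "class", methods = c("plsda", "rf"), boot = 15,
                         seed = 99)
  s2 <- select_signature(d, "class", methods = c("plsda", "rf"), boot = 15,
                         seed = 99)
  expect_identical(s1$tiers, s2$tiers)
  expect_identical(s1$accuracy, s2$accuracy)
  expect_identical(s1$results$plsda$trace, s2$results$plsda$trace)
})
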