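# Small in-code fixtures shared across test files.

# A tiny hand-sized table: 4 samples x 3 features, labels a,a,b,b.
tiny_table <- function() {
  tibble::tibble(
    sample_id = paste0("s", 1:4),
    class = c("a", "a", "b", "b"),
    f1 = c(1, 2, 3, 4),
    f2 = c(4, 3, 2, 1),
    f3 = c(1, 1, 2, 2)
  )
}

# A clearly separable two-feature toy: only f1 carries the class.
separable_toy <- function(n_per_class = 10, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    class = rep(c("a", "b"), each = n_per_class),
    f1 = c(rnorm(n_per_class, 0, 0.3), rnorm(n_per_class, 5, 0.3)),
    f2 = rnorm(2 * n_per_class)
  ))
}

# Brute-force oracles -----------------------------------------------------

# Balanced accuracy by direct confusion counts.
oracle_balanced_accuracy <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

# Lustgarten similarity via exhaustive enumeration: the chance term is the
# exact expected overlap of uniformly random subsets of the observed sizes,
# computed by enumerating every subset pair of the universe.
oracle_lustgarten <- function(a, b, universe) {
  p <- length(universe)
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0)
  subsets_a <- combn(universe, na, simplify = FALSE)
  subsets_b <- combn(universe, nb, simplify = FALSE)
  overlaps <- unlist(lapply(subsets_a, function(sa) {
    vapply(subsets_b, function(sb) length(intersect(sa, sb)), numeric(1))
  }))
  expected <- mean(overlaps)
  denom <- min(na, nb) - max(0, na + nb - p)
  if (denom == 0) return(0)
  (length(intersect(a, b)) - expected) / denom
}

# Median-rank aggregation by explicit counting (no rank()/order() shortcut
# beyond key comparison).
oracle_aggregate_ranks <- function(rank_matrix) {
  p <- ncol(rank_matrix)
  med <- apply(rank_matrix, 2, function(v) {
    s <- sort(v); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  })
  avg <- apply(rank_matrix, 2, mean)
  final <- integer(p)
  for (j in seq_len(p)) {
    smaller <- sum(
      med < med[j] |
      (med == med[j] & avg < avg[j]) |
      (med == med[j] & avg == avg[j] & seq_len(p) < j)
    )
    final[j] <- smaller + 1L
  }
  final
}

# Exhaustive linear-scan boundary for the half-interval search: with frozen
# per-rank verdicts, the boundary is the smallest rank declared not
# significant (p + 1 when every subset is significant).
oracle_search_boundary <- function(verdicts) {
  ns <- which(!verdicts)
  if (length(ns) == 0) length(verdicts) + 1L else min(ns)
}
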