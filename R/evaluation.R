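# Selection-quality metrics: chance-adjusted signature stability and
# PLS-DA model significance by response permutation.

#' Lustgarten chance-adjusted similarity between two feature sets
#'
#' Overlap between two selected feature sets, adjusted for the overlap
#' expected by chance between random sets of the same sizes drawn from a
#' p-feature universe, and normalised by the attainable range:
#' `(|a n b| - |a||b|/p) / (min(|a|,|b|) - max(0, |a|+|b|-p))`.
#' It accommodates sets of different sizes; the value of two identical
#' non-trivial sets is below 1 by the chance correction, and the expected
#' value over random selections is 0. By convention, an empty set (or a
#' degenerate denominator, e.g. both sets equal to the full universe)
#' yields 0.
#'
#' @param a,b Character vectors (or other atomic vectors) of feature ids.
#' @param p Size of the feature universe (total features; > 0).
#' @return A number in \[-1, 1\].
#' @examples
#' lustgarten_similarity(c("f1", "f2"), c("f1", "f2"), p = 10)  # 0.8
#' lustgarten_similarity(c("f1", "f2"), c("f3", "f4"), p = 10)  # -0.2
#' @export
lustgarten_similarity <- function(a, b, p) {
  if (p <= 0) stop("p must be positive", call. = FALSE)
  a <- unique(a)
  b <- unique(b)
  na <- length(a)
  nb <- length(b)
  if (na == 0L || nb == 0L) return(0)
  denom <- min(na, nb) - max(0L, na + nb - p)
  if (denom == 0) return(0)
  (length(intersect(a, b)) - na * nb / p) / denom
}

#' Harmonic mean of accuracy and stability
#'
#' The performance-robustness trade-off of a feature selection approach:
#' `2 * accuracy * stability / (accuracy + stability)`, 0 when the sum is 0.
#'
#' @param accuracy,stability Numbers (typically in \[0, 1\]).
#' @return The harmonic mean.
#' @export
selection_performance <- function(accuracy, stability) {
  s <- accuracy + stability
  if (!is.finite(s) || s == 0) return(0)
  2 * accuracy * stability / s
}

#' Stability of a feature selection approach
#'
#' Reruns a selector on 10 subsets each containing 90% of the samples (the
#' complements of a seeded stratified 10-fold partition) and averages the
#' Lustgarten similarity over all 45 pairs of resulting signatures. The
#' selector is also run once on the full dataset to obtain the accuracy
#' entering the harmonic-mean performance.
#'
#' @inheritParams select_signature
#' @param selector Function `(data, class, seed)` returning a list with
#'   `features` (character vector) and `accuracy` (number, or `NA`). See
#'   [signature_selector()] for a ready-made wrapper of
#'   [select_signature()].
#' @param n_subsets Number of subsets (default 10).
#' @return A `sig_stability` object: `signatures` (list), `similarity`
#'   (matrix), `stability`, `accuracy`, `performance`;
#'   [tidy()][generics::tidy] gives the pairwise similarities.
#' @export
signature_stability <- function(data, class = "class", selector,
                                positive_level = NULL, n_subsets = 10L,
                                seed = 1L) {
  x <- as_sig_data(data, class, positive_level)
  n <- nrow(x$X)
  p <- ncol(x$X)
  if (n < n_subsets) stop("need at least ", n_subsets, " samples", call. = FALSE)
  seeds <- .derive_seeds(seed, n_subsets + 2L)
  fold <- .with_seed(seeds[n_subsets + 1L], .stratified_folds(x$labels, n_subsets))
  df <- as.data.frame(x$X)
  df$.class <- x$labels
  df$sample_id <- rownames(x$X)
  sigs <- vector("list", n_subsets)
  for (j in seq_len(n_subsets)) {
    sub <- df[fold != j, , drop = FALSE]
    sigs[[j]] <- selector(sub, ".class", seeds[j])$features
  }
  sim <- diag(1, n_subsets)
  for (i in seq_len(n_subsets - 1L)) {
    for (j in seq(i + 1L, n_subsets)) {
      sim[i, j] <- sim[j, i] <- lustgarten_similarity(sigs[[i]], sigs[[j]], p)
    }
  }
  stability <- mean(sim[upper.tri(sim)])
  full <- selector(df, ".class", seeds[n_subsets + 2L])
  accuracy <- full$accuracy
  structure(
    list(signatures = sigs, similarity = sim, stability = stability,
         accuracy = accuracy, full_signature = full$features,
         performance = selection_performance(accuracy, stability)),
    class = "sig_stability"
  )
}

#' @export
print.sig_stability <- function(x, ...) {
  cat("<sig_stability> stability = ", round(x$stability, 4),
      ", accuracy = ", round(x$accuracy, 4),
      ", performance = ", round(x$performance, 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.sig_stability <- function(x, ...) {
  ut <- which(upper.tri(x$similarity), arr.ind = TRUE)
  tibble::tibble(
    subset_i = ut[, 1L], subset_j = ut[, 2L],
    similarity = x$similarity[ut]
  )
}

#' @export
glance.sig_stability <- function(x, ...) {
  tibble::tibble(stability = x$stability, accuracy = x$accuracy,
                 performance = x$performance,
                 mean_signature_size = mean(lengths(x$signatures)))
}

#' Wrap the signature selection as a stability selector
#'
#' Returns a closure suitable for [signature_stability()]: it runs
#' [select_signature()] with one classifier and reports the tier-S features
#' and the signature model's mean out-of-bag balanced accuracy (the full
#' model's accuracy when the signature is empty).
#'
#' @inheritParams select_signature
#' @param method A single classifier name.
#' @export
signature_selector <- function(method = "plsda", boot = 50L, alpha = 0.05,
                               max_rounds = 20L) {
  method <- match.arg(method, SIG_METHODS)
  function(data, class, seed) {
    fit <- select_signature(data, class = class, methods = method, boot = boot,
                            alpha = alpha, seed = seed, max_rounds = max_rounds)
    acc <- fit$accuracy
    a_s <- acc$balanced_accuracy[acc$model == "S"]
    a_full <- acc$balanced_accuracy[acc$model == "full"]
    list(features = fit$results[[method]]$signature,
         accuracy = if (is.na(a_s)) a_full else a_s)
  }
}

#' Permutation test of the PLS-DA model's predictive ability
#'
#' Assesses whether the cross-validated predictive ability (cumulative Q2Y)
#' of the PLS-DA model could have arisen by chance: the class labels are
#' randomly permuted `n_perm` times, a full PLS-DA fit (including automatic
#' component selection) is run on each permuted response, and the p-value is
#' the proportion of permuted Q2Y values greater than or equal to the
#' observed one (ties count, the conservative choice).
#'
#' @inheritParams fit_plsda
#' @param n_perm Number of response permutations (default 1000).
#' @return A `sig_q2y_test` object: `q2y_obs`, `r2y_obs`, `q2y_perm`
#'   (vector), `p_value`; with [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
q2y_permutation_test <- function(data, class = "class", positive_level = NULL,
                                 n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  x <- as_sig_data(data, class, positive_level)
  seeds <- .derive_seeds(seed, n_perm + 1L)
  obs <- .with_seed(seeds[n_perm + 1L],
                    .fit_plsda_engine(x$X, x$labels, x$positive))
  q2y_perm <- vapply(seq_len(n_perm), function(i) {
    .with_seed(seeds[i], {
      perm_labels <- sample(x$labels)
      .fit_plsda_engine(x$X, perm_labels, x$positive)$q2y_cum
    })
  }, numeric(1))
  structure(
    list(q2y_obs = obs$q2y_cum, r2y_obs = obs$r2y_cum,
         ncomp_obs = obs$r_admitted, q2y_perm = q2y_perm,
         p_value = mean(q2y_perm >= obs$q2y_cum), n_perm = n_perm),
    class = "sig_q2y_test"
  )
}

#' @export
print.sig_q2y_test <- function(x, ...) {
  cat("Q2Y permutation test: Q2Y = ", round(x$q2y_obs, 4),
      ", p = ", format(x$p_value, digits = 4), " (", x$n_perm,
      " permutations)\n", sep = "")
  invisible(x)
}

#' @export
tidy.sig_q2y_test <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$q2y_perm), q2y_perm = x$q2y_perm)
}

#' @export
glance.sig_q2y_test <- function(x, ...) {
  tibble::tibble(q2y_obs = x$q2y_obs, r2y_obs = x$r2y_obs,
                 ncomp = x$ncomp_obs, n_perm = x$n_perm, p_value = x$p_value)
}

#' @export
autoplot.sig_q2y_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$q2y_perm)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$q2y_obs, colour = "red") +
    ggplot2::labs(x = "Q2Y (permuted responses)", y = "count",
                  title = sprintf("Observed Q2Y = %.3f, p = %.4g",
                                  object$q2y_obs, object$p_value)) +
    ggplot2::theme_minimal()
}
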