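# Bootstrap resampling with out-of-bag evaluation.

#' Stratified bootstrap train/test splits
#'
#' Draws `boot` bootstrap resamples of the sample indices, stratified by
#' class (each class is resampled with replacement to its own size, so the
#' training multiset always has the original class balance). The test set of
#' a split is the out-of-bag set: samples never drawn into training. Draws
#' whose out-of-bag set is empty or single-class are redrawn (at most 100
#' retries per split) because balanced accuracy is undefined otherwise.
#'
#' @param labels Character vector of two-level class labels.
#' @param boot Number of bootstrap splits (>= 2; the method default is 50).
#' @param seed Integer seed; the same seed yields the identical split list.
#' @return List of `boot` lists with integer fields `train` (length n,
#'   with replacement) and `test` (out-of-bag indices, both classes present).
#' @examples
#' sp <- bootstrap_splits(rep(c("a", "b"), each = 10), boot = 5, seed = 1)
#' lengths(lapply(sp, `[[`, "test"))
#' @export
bootstrap_splits <- function(labels, boot = 50L, seed = 1L) {
  stopifnot(boot >= 2L)
  labels <- as.character(labels)
  n <- length(labels)
  idx_by_class <- split(seq_len(n), labels)
  if (length(idx_by_class) != 2L) stop("labels must have two levels", call. = FALSE)
  .with_seed(seed, lapply(seq_len(boot), function(k) {
    for (try in seq_len(100L)) {
      train <- unlist(lapply(idx_by_class, function(ix) {
        sample(ix, length(ix), replace = TRUE)
      }), use.names = FALSE)
      test <- setdiff(seq_len(n), train)
      if (length(test) > 0L && length(unique(labels[test])) == 2L) {
        return(list(train = train, test = test))
      }
    }
    stop("could not draw a two-class out-of-bag set in 100 tries ",
         "(dataset too small or too imbalanced)", call. = FALSE)
  }))
}

#' Balanced prediction accuracy
#'
#' The mean of sensitivity and specificity, robust to class imbalance: a
#' constant prediction scores 0.5 whatever the class proportions.
#'
#' @param truth Character vector of true labels (must contain both classes).
#' @param predicted Character vector of predicted labels, same length.
#' @param positive_level The level counted as "positive" for sensitivity.
#' @return A proportion in \[0, 1\].
#' @examples
#' balanced_accuracy(c("a", "a", "b", "b"), c("a", "b", "b", "b"), "b")
#' @export
balanced_accuracy <- function(truth, predicted, positive_level) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted), length(truth) >= 1L)
  if (length(unique(truth)) < 2L) {
    stop("truth contains a single class; balanced accuracy undefined",
         call. = FALSE)
  }
  pos <- truth == positive_level
  sens <- mean(predicted[pos] == positive_level)
  spec <- mean(predicted[!pos] != positive_level)
  (sens + spec) / 2
}

#' Fit one classifier per bootstrap split
#'
#' Step 1 of the selection engine: trains `boot` models of one classifier
#' type on stratified bootstrap training sets, computes each model's feature
#' ranking (VIP for PLS-DA, error-rate importance for Random Forest, squared
#' weights for SVM) and its balanced accuracy on the out-of-bag test set.
#' These fits are trained once and reused for every subsequent permutation
#' evaluation -- no model is ever refitted during subset-significance
#' testing.
#'
#' @inheritParams select_signature
#' @param method One of `"plsda"`, `"rf"`, `"svm"`.
#' @return A `sig_boot_fits` object: splits, trained models, a `boot` x p
#'   rank matrix, and per-split out-of-bag balanced accuracies.
#' @export
bootstrap_fits <- function(data, class = "class", method = "plsda",
                           positive_level = NULL, boot = 50L, seed = 1L) {
  x <- as_sig_data(data, class, positive_level)
  method <- match.arg(method, SIG_METHODS)
  p <- ncol(x$X)
  if (p == 0L) stop("no features to fit", call. = FALSE)
  seeds <- .derive_seeds(seed, boot + 1L)
  splits <- bootstrap_splits(x$labels, boot, seeds[1L])
  models <- vector("list", boot)
  rank_matrix <- matrix(NA_integer_, boot, p, dimnames = list(NULL, colnames(x$X)))
  accuracy <- numeric(boot)
  for (k in seq_len(boot)) {
    sp <- splits[[k]]
    m <- .fit_classifier(x$X[sp$train, , drop = FALSE], x$labels[sp$train],
                         x$positive, method, seed = seeds[k + 1L])
    models[[k]] <- m
    rank_matrix[k, ] <- rank_features(.importance_classifier(m))
    pred <- .predict_classifier(m, x$X[sp$test, , drop = FALSE])
    accuracy[k] <- balanced_accuracy(x$labels[sp$test], pred, x$positive)
  }
  structure(
    list(x = x, method = method, boot = boot, splits = splits, models = models,
         rank_matrix = rank_matrix, accuracy = accuracy,
         feature_ids = colnames(x$X)),
    class = "sig_boot_fits"
  )
}

#' @export
print.sig_boot_fits <- function(x, ...) {
  cat("<sig_boot_fits> ", x$boot, " ", x$method, " bootstrap fits on ",
      length(x$feature_ids), " features; mean OOB balanced accuracy ",
      round(mean(x$accuracy), 4), "\n", sep = "")
  invisible(x)
}

# Mean OOB balanced accuracy of `method` restricted to `features`,
# over `boot` fresh bootstraps. NA when `features` is empty.
.oob_accuracy <- function(x, features, method, boot, seed) {
  if (length(features) == 0L) return(NA_real_)
  xr <- restrict_features(x, features)
  fits <- bootstrap_fits(xr, method = method, boot = boot, seed = seed)
  mean(fits$accuracy)
}
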