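# Uniform fit / predict / importance contract over the three wrapped
# classifiers. PLS-DA has its own engine (plsda.R); Random Forest and linear
# SVM delegate to the reference implementations (randomForest, e1071) with
# the fixed hyperparameters of the method: 500 trees and mtry = floor(sqrt(p))
# for the forest, cost = 1 and a linear kernel (on centred/scaled features)
# for the SVM. Features are scaled for PLS-DA and SVM only; the forest sees
# raw intensities.

SIG_METHODS <- c("plsda", "rf", "svm")

.fit_rf_engine <- function(X, labels, positive) {
  negative <- setdiff(unique(labels), positive)
  yfac <- factor(labels, levels = c(negative, positive))
  p <- ncol(X)
  fit <- randomForest::randomForest(
    x = as.data.frame(X), y = yfac,
    ntree = 500L, mtry = max(1L, floor(sqrt(p))),
    importance = TRUE
  )
  imp <- randomForest::importance(fit, type = 1L)[, 1L]
  structure(list(
    method = "rf", feature_ids = colnames(X), fit = fit,
    importance = stats::setNames(as.numeric(imp), colnames(X)),
    positive = positive, negative = negative
  ), class = "sig_rf_engine")
}

.fit_svm_engine <- function(X, labels, positive) {
  negative <- setdiff(unique(labels), positive)
  yfac <- factor(labels, levels = c(negative, positive))
  sc <- .scale_fit(X)
  Xs <- .scale_apply(X, sc)
  fit <- e1071::svm(x = Xs, y = yfac, kernel = "linear", cost = 1, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))  # primal weights on the scaled space
  w_full <- stats::setNames(rep(0, ncol(X)), colnames(X))
  w_full[colnames(fit$SV)] <- w
  structure(list(
    method = "svm", feature_ids = colnames(X), fit = fit, scaling = sc,
    weights = w_full, importance = w_full^2,
    positive = positive, negative = negative
  ), class = "sig_svm_engine")
}

# method dispatch used by the selection engine; `seed` scopes the stochastic
# fits (RF bagging, PLS-DA CV folds); SVM fitting is deterministic.
.fit_classifier <- function(X, labels, positive, method, seed = NULL) {
  method <- match.arg(method, SIG_METHODS)
  .with_seed(seed, switch(method,
    plsda = .fit_plsda_engine(X, labels, positive),
    rf = .fit_rf_engine(X, labels, positive),
    svm = .fit_svm_engine(X, labels, positive)
  ))
}

.predict_classifier <- function(model, Xnew) {
  switch(model$method,
    plsda = .predict_plsda_engine(model, Xnew),
    rf = {
      Xnew <- Xnew[, model$feature_ids, drop = FALSE]
      as.character(stats::predict(model$fit, newdata = as.data.frame(Xnew)))
    },
    svm = {
      Xnew <- Xnew[, model$feature_ids, drop = FALSE]
      as.character(stats::predict(model$fit, newdata = .scale_apply(Xnew, model$scaling)))
    }
  )
}

# Ranking metric per classifier: VIP (PLS-DA), error-rate-based variable
# importance (RF), squared primal weights (SVM). Larger = more important.
.importance_classifier <- function(model) {
  switch(model$method,
    plsda = stats::setNames(model$vip, model$feature_ids),
    model$importance
  )
}

#' Rank features by decreasing importance
#'
#' Converts an importance metric (larger = more important) into dense ranks
#' 1..p with rank 1 the most important feature. Ties are broken by ascending
#' feature index, so the output is always a permutation of 1..p.
#'
#' @param metric Numeric vector of importance values (one per feature).
#' @return Integer vector of ranks, same length and names as `metric`.
#' @examples
#' rank_features(c(f1 = 0.2, f2 = 0.9, f3 = 0.5))  # 3 1 2
#' @export
rank_features <- function(metric) {
  stopifnot(is.numeric(metric))
  ord <- order(-metric, seq_along(metric))
  ranks <- integer(length(metric))
  ranks[ord] <- seq_along(metric)
  names(ranks) <- names(metric)
  ranks
}
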