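# PLS1 discriminant-analysis engine: NIPALS with automatic component
# admission (R2Y >= 1% and 7-fold cross-validated Q2Y >= 0, or >= 5% when
# n < 100), Wold VIP, and {-0.5, +0.5} response coding.

.scale_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  flagged <- !is.finite(sd) | sd == 0
  sd[flagged] <- 1  # zero-variance guard: centre only
  list(mu = mu, sd = sd, flagged = flagged)
}

.scale_apply <- function(X, sc) {
  sweep(sweep(X, 2L, sc$mu, "-"), 2L, sc$sd, "/")
}

# Sequential PLS1 components by NIPALS deflation of X and y.
# Xs: scaled matrix; yc: centred response. Returns weights W (columns unit
# norm), loadings P, scores Tm, y-loadings c, and per-component score norms.
.nipals <- function(Xs, yc, r_max) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  W <- matrix(0, p, 0)
  P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  cvec <- numeric(0)
  tt <- numeric(0)
  Xh <- Xs
  yh <- yc
  for (h in seq_len(r_max)) {
    w <- crossprod(Xh, yh)
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw < 1e-12) break
    w <- w / nw
    t_h <- drop(Xh %*% w)
    tt_h <- sum(t_h^2)
    if (tt_h < 1e-12) break
    c_h <- sum(t_h * yh) / tt_h
    p_h <- drop(crossprod(Xh, t_h)) / tt_h
    Xh <- Xh - tcrossprod(t_h, p_h)
    yh <- yh - c_h * t_h
    W <- cbind(W, w, deparse.level = 0)
    P <- cbind(P, p_h, deparse.level = 0)
    Tm <- cbind(Tm, t_h, deparse.level = 0)
    cvec <- c(cvec, c_h)
    tt <- c(tt, tt_h)
  }
  list(W = W, P = P, Tm = Tm, c = cvec, tt = tt, r = ncol(W))
}

.pls_coef <- function(nip, r) {
  W <- nip$W[, seq_len(r), drop = FALSE]
  P <- nip$P[, seq_len(r), drop = FALSE]
  C <- nip$c[seq_len(r)]
  drop(W %*% solve(crossprod(P, W), C))
}

# Stratified fold assignment; every training part keeps both classes because
# each class with >= 2 members is spread over >= 2 folds.
.stratified_folds <- function(labels, k) {
  n <- length(labels)
  k <- min(k, n)
  fold <- integer(n)
  for (lev in unique(labels)) {
    idx <- which(labels == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Full PLS-DA fit on a (sub)matrix. Returns the model list used by the
# selection engine; `labels`/`positive` drive the response coding and the
# majority-class fallback. Uses the current RNG stream for CV folds.
.fit_plsda_engine <- function(X, labels, positive, cv_folds = 7L) {
  n <- nrow(X)
  p <- ncol(X)
  if (p == 0L) stop("cannot fit PLS-DA on a 0-feature table", call. = FALSE)
  negative <- setdiff(unique(labels), positive)
  y <- ifelse(labels == positive, 0.5, -0.5)
  sc <- .scale_fit(X)
  Xs <- .scale_apply(X, sc)
  ybar <- mean(y)
  yc <- y - ybar
  ssy <- sum(yc^2)  # RSS_0 = (n - 1) var(y)
  r_cap <- max(1L, min(10L, n - 1L, p))
  full <- .nipals(Xs, yc, r_cap)
  n_tab <- table(labels)
  majority <- if (n_tab[positive] >= n_tab[negative]) positive else negative

  if (full$r == 0L || ssy < 1e-12) {
    # degenerate (constant X or constant y): no component can be formed
    return(structure(list(
      method = "plsda", feature_ids = colnames(X), scaling = sc,
      positive = positive, negative = negative, majority = majority,
      ybar = ybar, r = 0L, r_admitted = 0L, informative = FALSE,
      degenerate = TRUE, coef = rep(0, p), vip = rep(0, p),
      r2y = numeric(0), q2y = numeric(0), q2y_cum = NA_real_,
      r2y_cum = NA_real_
    ), class = "sig_plsda_engine"))
  }

  r_avail <- full$r
  r2y <- full$c^2 * full$tt / ssy
  # residual y after h components (NIPALS deflates y): RSS_h
  yfit <- full$Tm %*% diag(full$c, r_avail, r_avail)
  res <- yc - t(apply(yfit, 1L, cumsum))
  if (r_avail == 1L) res <- yc - yfit
  rss <- c(ssy, colSums(as.matrix(res)^2))

  # 7-fold CV predictions per component count -> PRESS_h
  fold <- .stratified_folds(labels, cv_folds)
  k <- max(fold)
  press_mat <- matrix(NA_real_, n, r_avail)
  for (j in seq_len(k)) {
    hold <- fold == j
    Xtr <- Xs[!hold, , drop = FALSE]
    ytr <- yc[!hold]
    ytr_bar <- mean(ytr)
    nip_j <- .nipals(Xtr, ytr - ytr_bar, r_avail)
    for (h in seq_len(r_avail)) {
      h_eff <- min(h, nip_j$r)
      pred <- if (h_eff == 0L) {
        rep(ytr_bar, sum(hold))
      } else {
        drop(Xs[hold, , drop = FALSE] %*% .pls_coef(nip_j, h_eff)) + ytr_bar
      }
      press_mat[hold, h] <- (yc[hold] - pred)^2
    }
  }
  press <- colSums(press_mat)
  q2y <- 1 - press / rss[seq_len(r_avail)]

  # greedy admission
  thresh <- if (n < 100L) 0.05 else 0
  r_adm <- 0L
  for (h in seq_len(r_avail)) {
    if (r2y[h] >= 0.01 && q2y[h] >= thresh) r_adm <- h else break
  }
  informative <- r_adm > 0L
  r_use <- if (informative) r_adm else 1L  # forced component for ranking

  coef <- .pls_coef(full, r_use)
  ss <- full$c[seq_len(r_use)]^2 * full$tt[seq_len(r_use)]
  W <- full$W[, seq_len(r_use), drop = FALSE]  # columns already unit norm
  vip <- sqrt(p * drop(W^2 %*% ss) / sum(ss))
  q2y_cum <- 1 - prod(1 - q2y[seq_len(r_use)])
  r2y_cum <- sum(r2y[seq_len(r_use)])

  structure(list(
    method = "plsda", feature_ids = colnames(X), scaling = sc,
    positive = positive, negative = negative, majority = majority,
    ybar = ybar, r = r_use, r_admitted = r_adm, informative = informative,
    degenerate = FALSE, coef = coef, vip = vip,
    weights = W, loadings = full$P[, seq_len(r_use), drop = FALSE],
    scores = full$Tm[, seq_len(r_use), drop = FALSE],
    y_loadings = full$c[seq_len(r_use)],
    r2y = r2y[seq_len(r_use)], q2y = q2y[seq_len(r_use)],
    press = press[seq_len(r_use)], rss = rss[seq_len(r_use) + 1L],
    r2y_cum = r2y_cum, q2y_cum = q2y_cum
  ), class = "sig_plsda_engine")
}

.predict_plsda_engine <- function(model, Xnew) {
  ids <- model$feature_ids
  if (!identical(colnames(Xnew), ids)) {
    if (!all(ids %in% colnames(Xnew))) {
      stop("prediction table lacks training feature(s): ",
           paste(setdiff(ids, colnames(Xnew)), collapse = ", "), call. = FALSE)
    }
    Xnew <- Xnew[, ids, drop = FALSE]
  }
  if (!model$informative) {
    return(rep(model$majority, nrow(Xnew)))
  }
  yhat <- drop(.scale_apply(Xnew, model$scaling) %*% model$coef) + model$ybar
  unname(ifelse(yhat > 0, model$positive, model$negative))  # tie (0) -> negative
}

#' Cumulative Q2Y from per-component values
#'
#' The cross-validated predictive ability of a multi-component PLS model:
#' `1 - prod(1 - q2y_h)` over the fitted components.
#'
#' @param q2y Numeric vector of per-component Q2Y values.
#' @return A single number, at most 1.
#' @examples
#' cumulative_q2y(c(0.5, 0.2))  # 0.6
#' @export
cumulative_q2y <- function(q2y) {
  stopifnot(is.numeric(q2y))
  1 - prod(1 - q2y)
}

#' Fit a PLS-DA model with automatic component selection
#'
#' Partial least squares discriminant analysis for a two-class response:
#' features are mean-centred and unit-variance scaled (zero-variance features
#' are centred only), the class is coded as a numeric response in
#' \{-0.5, +0.5\}, and PLS1 components are extracted with NIPALS. Components
#' are admitted greedily while the component explains at least 1% of the
#' response variance (R2Y_h >= 0.01) and its 7-fold cross-validated Q2Y_h =
#' 1 - PRESS_h / RSS_(h-1) is at least 0 (at least 0.05 when n < 100). When
#' no component passes, the model is flagged non-informative: one component
#' is still fitted so that feature importance (VIP) remains defined, but
#' predictions fall back to the training majority class.
#'
#' @inheritParams as_sig_data
#' @param seed Integer seed for the cross-validation fold assignment.
#' @return A `sig_plsda` object with [tidy()][generics::tidy] (per-feature
#'   VIP, coefficient, rank), [glance()][generics::glance] (components, R2Y,
#'   cumulative Q2Y, informativeness) and [predict()] methods.
#' @examples
#' d <- simulate_planted(n_per_class = 10, p = 5, d = 3, seed = 1)
#' fit <- fit_plsda(d, class = "class", seed = 1)
#' glance(fit)
#' @export
fit_plsda <- function(data, class, positive_level = NULL, seed = 1L) {
  sd_ <- as_sig_data(data, class, positive_level)
  engine <- .with_seed(seed, .fit_plsda_engine(sd_$X, sd_$labels, sd_$positive))
  structure(
    list(engine = engine, class_column = if (is.character(class)) class else "class",
         n = nrow(sd_$X), p = ncol(sd_$X), seed = seed),
    class = "sig_plsda"
  )
}

#' @export
print.sig_plsda <- function(x, ...) {
  e <- x$engine
  cat("PLS-DA (", x$n, " x ", x$p, "): ", e$r_admitted, " admitted component(s)",
      if (!e$informative) " [non-informative]", "\n", sep = "")
  if (e$r >= 1L && !e$degenerate) {
    cat("  R2Y(cum) = ", round(e$r2y_cum, 4),
        ", Q2Y(cum) = ", round(e$q2y_cum, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Per-feature VIP values of a fitted PLS-DA model
#'
#' Variable importance in projection, the Wold form: each feature's squared
#' weight per component, weighted by the component's explained response
#' variance and normalised so that the squared VIPs sum to the number of
#' features.
#'
#' @param model A `sig_plsda` object from [fit_plsda()].
#' @return Named numeric vector of VIP values (all >= 0).
#' @export
vip <- function(model) {
  e <- if (inherits(model, "sig_plsda")) model$engine else model
  stopifnot(inherits(e, "sig_plsda_engine"))
  stats::setNames(e$vip, e$feature_ids)
}

#' Predict class labels from a fitted PLS-DA model
#'
#' @param object A `sig_plsda` object.
#' @param newdata Data frame containing (at least) the training feature
#'   columns.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `y_hat` (numeric score; `NA` for a
#'   non-informative model) and `predicted` (class label).
#' @export
predict.sig_plsda <- function(object, newdata, ...) {
  e <- object$engine
  stopifnot(is.data.frame(newdata))
  miss <- setdiff(e$feature_ids, names(newdata))
  if (length(miss) > 0L) {
    stop("newdata lacks training feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(newdata[e$feature_ids])
  storage.mode(X) <- "double"
  ids <- if ("sample_id" %in% names(newdata)) {
    as.character(newdata$sample_id)
  } else {
    paste0("s", seq_len(nrow(X)))
  }
  rownames(X) <- ids
  yhat <- if (e$informative) {
    drop(.scale_apply(X, e$scaling) %*% e$coef) + e$ybar
  } else {
    rep(NA_real_, nrow(X))
  }
  tibble::tibble(
    sample_id = ids,
    y_hat = unname(yhat),
    predicted = .predict_plsda_engine(e, X)
  )
}

#' @export
tidy.sig_plsda <- function(x, ...) {
  e <- x$engine
  tibble::tibble(
    feature_id = e$feature_ids,
    vip = e$vip,
    coefficient = e$coef,
    rank = rank_features(e$vip)
  )
}

#' @export
glance.sig_plsda <- function(x, ...) {
  e <- x$engine
  tibble::tibble(
    n = x$n, p = x$p,
    ncomp = e$r_admitted,
    informative = e$informative,
    r2y_cum = e$r2y_cum,
    q2y_cum = e$q2y_cum
  )
}
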