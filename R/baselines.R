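# Comparator baselines sharing the classifier and metric machinery:
# VIP filtering and recursive feature elimination (RFE).

#' Filter features by PLS-DA VIP
#'
#' Fits one PLS-DA model on the full dataset and keeps every feature whose
#' VIP is greater than or equal to the threshold (the two conventional
#' presets are 1 and 1.5). When the model is non-informative (no component
#' admitted) the filter returns an empty set with a warning, since the VIP
#' values then carry no predictive meaning.
#'
#' @inheritParams fit_plsda
#' @param threshold Positive VIP cut-off (default 1).
#' @return Tibble with `feature_id`, `vip`, sorted by decreasing VIP
#'   (only the kept features).
#' @export
vip_filter <- function(data, class = "class", threshold = 1,
                       positive_level = NULL, seed = 1L) {
  stopifnot(threshold > 0)
  fit <- fit_plsda(data, class, positive_level, seed = seed)
  if (!fit$engine$informative) {
    warning("PLS-DA model is non-informative; returning an empty set",
            call. = FALSE)
    return(tibble::tibble(feature_id = character(0), vip = numeric(0)))
  }
  v <- vip(fit)
  keep <- v >= threshold
  out <- tibble::tibble(feature_id = names(v)[keep], vip = unname(v[keep]))
  dplyr::arrange(out, dplyr::desc(.data$vip))
}

#' RFE elimination schedule
#'
#' The sequence of feature-set sizes visited by [rfe_select()]: starting
#' from p, each iteration removes `max(1, floor(0.2 * p_current))` features
#' (the worst-ranked 20%), down to a single feature.
#'
#' @param p Starting number of features.
#' @return Integer vector of sizes, strictly decreasing to 1.
#' @examples
#' rfe_schedule(10)  # 10 8 7 6 5 4 3 2 1
#' @export
rfe_schedule <- function(p) {
  stopifnot(p >= 1L)
  sizes <- as.integer(p)
  while (p > 1L) {
    p <- p - max(1L, floor(0.2 * p))
    sizes <- c(sizes, as.integer(p))
  }
  sizes
}

#' Recursive feature elimination with bootstrap out-of-bag evaluation
#'
#' The comparator wrapper: at each iteration, `boot` bootstrap models of one
#' classifier are fitted on the current feature set, the mean out-of-bag
#' balanced accuracy is recorded, the per-bootstrap rankings are aggregated
#' by the median, and the `max(1, floor(0.2 * p))` worst-ranked features are
#' removed. Bootstraps are redrawn at each iteration. The selected set is
#' the visited size with the best mean accuracy (ties resolved toward the
#' smaller size).
#'
#' @inheritParams select_signature
#' @inheritParams bootstrap_fits
#' @return A `sig_rfe` object: `trace` (tibble: size, balanced_accuracy,
#'   features list-column), `selected_size`, `selected` (feature ids);
#'   [tidy()][generics::tidy] returns the trace, `autoplot()` the
#'   accuracy-vs-size curve.
#' @export
rfe_select <- function(data, class = "class", method = "plsda",
                       positive_level = NULL, boot = 50L, seed = 1L) {
  x <- as_sig_data(data, class, positive_level)
  method <- match.arg(method, SIG_METHODS)
  sizes <- rfe_schedule(ncol(x$X))
  seeds <- .derive_seeds(seed, length(sizes))
  cur <- x
  rows <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    fits <- bootstrap_fits(cur, method = method, boot = boot, seed = seeds[i])
    ranks <- aggregate_ranks(fits$rank_matrix)
    rows[[i]] <- tibble::tibble(
      size = sizes[i],
      balanced_accuracy = mean(fits$accuracy),
      features = list(colnames(cur$X))
    )
    if (i < length(sizes)) {
      keep <- names(sort(ranks))[seq_len(sizes[i + 1L])]  # never drops rank 1
      cur <- restrict_features(cur, keep)
    }
  }
  trace <- dplyr::bind_rows(rows)
  best <- which(trace$balanced_accuracy == max(trace$balanced_accuracy))
  best <- best[which.min(trace$size[best])]
  structure(
    list(trace = trace, method = method,
         selected_size = trace$size[best],
         selected = trace$features[[best]],
         config = list(boot = boot, seed = seed)),
    class = "sig_rfe"
  )
}

#' @export
print.sig_rfe <- function(x, ...) {
  cat("RFE (", x$method, "): selected ", x$selected_size, " feature",
      if (x$selected_size != 1L) "s", " {",
      paste(utils::head(x$selected, 8L), collapse = ", "),
      if (x$selected_size > 8L) ", ...", "}\n", sep = "")
  invisible(x)
}

#' @export
tidy.sig_rfe <- function(x, ...) {
  dplyr::select(x$trace, "size", "balanced_accuracy")
}

#' @export
glance.sig_rfe <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    selected_size = x$selected_size,
    best_accuracy = max(x$trace$balanced_accuracy),
    n_iterations = nrow(x$trace)
  )
}

#' @export
autoplot.sig_rfe <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$size, y = .data$balanced_accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_size, colour = "red",
                        linetype = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "feature-set size", y = "mean OOB balanced accuracy",
                  title = paste0("RFE (", object$method, ")")) +
    ggplot2::theme_minimal()
}
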