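# The selection engine: rank aggregation, permutation-based subset
# significance, half-interval search over ranked subsets, iterated rounds,
# and tier assignment.

#' Aggregate per-bootstrap feature rankings by the median
#'
#' The final ranking of a selection round: each feature's rank is the dense
#' rank of the median of its per-bootstrap ranks. Median ties are broken by
#' the mean rank, remaining ties by ascending feature index, so the result
#' is always a permutation of 1..p.
#'
#' @param rank_matrix Integer matrix, one row per bootstrap, each row a
#'   permutation of 1..p.
#' @return Integer vector of final ranks (named when the matrix has column
#'   names).
#' @examples
#' aggregate_ranks(rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3)))
#' @export
aggregate_ranks <- function(rank_matrix) {
  rank_matrix <- as.matrix(rank_matrix)
  p <- ncol(rank_matrix)
  if (any(apply(rank_matrix, 1L, function(r) !setequal(r, seq_len(p))))) {
    stop("every row must be a permutation of 1..p", call. = FALSE)
  }
  med <- apply(rank_matrix, 2L, stats::median)
  avg <- colMeans(rank_matrix)
  ord <- order(med, avg, seq_len(p))
  final <- integer(p)
  final[ord] <- seq_len(p)
  names(final) <- colnames(rank_matrix)
  final
}

#' Permute candidate-subset intensities in a test table
#'
#' For each feature in `subset`, its values across the rows of `X` are
#' independently shuffled (one fresh permutation per feature), destroying
#' that feature's association with the class while preserving its marginal
#' distribution. Features outside `subset` are untouched. This is applied to
#' out-of-bag test sets only; training matrices are never mutated.
#'
#' @param X Numeric matrix (test samples x features) with column names.
#' @param subset Character vector of feature ids to permute.
#' @param seed Optional integer seed; by default the current RNG stream is
#'   used (callers seed the enclosing evaluation).
#' @return The matrix with the subset columns rearranged.
#' @export
permute_subset <- function(X, subset, seed = NULL) {
  stopifnot(is.matrix(X))
  subset <- as.character(subset)
  unknown <- setdiff(subset, colnames(X))
  if (length(unknown) > 0L) {
    stop("unknown feature id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  .with_seed(seed, {
    for (f in subset) {
      X[, f] <- X[sample.int(nrow(X)), f]
    }
    X
  })
}

#' Significance verdict from permuted and reference accuracies
#'
#' The decision rule of the permutation test, applied to paired accuracy
#' records: the candidate subset is declared *not* significant when the
#' proportion of bootstraps whose permuted accuracy is greater than or equal
#' to the reference accuracy exceeds `alpha` (strictly); it is significant
#' when the proportion is at most `alpha`.
#'
#' @param accuracy_perm Numeric vector of balanced accuracies after
#'   permuting the candidate subset in the test sets.
#' @param accuracy_ref Numeric vector of the unpermuted (reference)
#'   accuracies, same length.
#' @param alpha Significance threshold (default 0.05).
#' @return List with `significant` (logical) and `proportion` (the
#'   non-exceedance proportion).
#' @examples
#' subset_verdict(c(0.5, 0.9, 0.4), c(0.8, 0.8, 0.8), alpha = 0.05)
#' @export
subset_verdict <- function(accuracy_perm, accuracy_ref, alpha = 0.05) {
  stopifnot(length(accuracy_perm) == length(accuracy_ref), length(accuracy_ref) >= 1L)
  proportion <- mean(accuracy_perm >= accuracy_ref)
  list(significant = proportion <= alpha, proportion = proportion)
}

#' Test whether a feature subset significantly contributes to prediction
#'
#' For each of the frozen bootstrap fits, the candidate features are permuted
#' in the out-of-bag test set, the (already trained) model predicts the
#' permuted set, and the permuted balanced accuracy is compared with the
#' unpermuted one. No model is refitted. See [subset_verdict()] for the
#' decision rule.
#'
#' @param fits A `sig_boot_fits` object from [bootstrap_fits()].
#' @param subset Character vector of candidate feature ids.
#' @param alpha Significance threshold (default 0.05).
#' @param seed Optional integer seed scoping the fresh permutations.
#' @return List with `significant`, `proportion` and `accuracy_perm`.
#' @export
subset_significance <- function(fits, subset, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(fits, "sig_boot_fits"))
  subset <- as.character(subset)
  x <- fits$x
  acc_perm <- .with_seed(seed, vapply(seq_len(fits$boot), function(k) {
    test <- fits$splits[[k]]$test
    Xp <- permute_subset(x$X[test, , drop = FALSE], subset)
    pred <- .predict_classifier(fits$models[[k]], Xp)
    balanced_accuracy(x$labels[test], pred, x$positive)
  }, numeric(1)))
  out <- subset_verdict(acc_perm, fits$accuracy, alpha)
  out$accuracy_perm <- acc_perm
  out
}

#' Half-interval search for the largest non-significant ranked subset
#'
#' Candidates are rank positions over the aggregated ranking; the candidate
#' subset at rank f is every feature with rank >= f (so rank 1 means
#' "permute everything"). The search maintains the rank of the last
#' significant candidate (`h`, sentinel 0) and of the last non-significant
#' candidate (`l`, sentinel p + 1); the first candidate is rank 1, each next
#' candidate is the midpoint of the open interval (h, l) with half rounded
#' away from zero, and the search stops when the interval is empty. The
#' boundary `f_ns` (= final `l`) is the lowest rank whose subset is not
#' significant; the round's significant set is every feature of rank
#' < `f_ns` (empty when `f_ns` = 1).
#'
#' @param p Number of rank positions (features in the current table).
#' @param test Function taking a candidate rank f and returning a list with
#'   elements `significant` (logical) and `proportion` (see
#'   [subset_significance()]).
#' @return List with `f_ns`, `significant_ranks` (integer vector, possibly
#'   empty) and `trace` (tibble: candidate rank, subset size, proportion,
#'   verdict, in visit order).
#' @export
half_interval_search <- function(p, test) {
  p <- as.integer(p)
  stopifnot(p >= 1L, is.function(test))
  h <- 0L
  l <- p + 1L
  f <- 1L
  cand <- integer(0)
  prop <- numeric(0)
  verdict <- logical(0)
  repeat {
    res <- test(f)
    cand <- c(cand, f)
    prop <- c(prop, res$proportion)
    verdict <- c(verdict, isTRUE(res$significant))
    if (isTRUE(res$significant)) h <- f else l <- f
    if (l - h <= 1L) break
    nxt <- as.integer(.round_half_up((h + l) / 2))
    if (nxt <= h) nxt <- h + 1L
    if (nxt >= l) nxt <- l - 1L
    f <- nxt
  }
  list(
    f_ns = l,
    significant_ranks = seq_len(l - 1L),
    trace = tibble::tibble(
      candidate_rank = cand,
      subset_size = p - cand + 1L,
      proportion = prop,
      significant = verdict
    )
  )
}

#' One selection round: resample, rank, test
#'
#' Runs the three engine steps once on the current feature table: bootstrap
#' fits ([bootstrap_fits()]), median rank aggregation ([aggregate_ranks()]),
#' and the half-interval search over permutation-tested ranked subsets. When
#' the significant set is non-empty it is returned as registered; when it is
#' empty, the most important half of the features (ceiling(p/2) lowest
#' ranks) is returned unregistered, so the next round works on a smaller
#' table without crediting any feature.
#'
#' @inheritParams select_signature
#' @inheritParams bootstrap_fits
#' @return List with `features` (ids, in ascending final rank),
#'   `registered` (logical), `ranks` (final rank per feature id), `fits`,
#'   and `trace`.
#' @export
selection_round <- function(data, class = "class", method = "plsda",
                            positive_level = NULL, boot = 50L, alpha = 0.05,
                            seed = 1L) {
  x <- as_sig_data(data, class, positive_level)
  p <- ncol(x$X)
  if (p < 1L) stop("the table has no feature left", call. = FALSE)
  seeds <- .derive_seeds(seed, 2L)
  fits <- bootstrap_fits(x, method = method, boot = boot, seed = seeds[1L])
  final_ranks <- aggregate_ranks(fits$rank_matrix)
  perm_seeds <- .derive_seeds(seeds[2L], p)
  search <- half_interval_search(p, function(f) {
    subset <- names(final_ranks)[final_ranks >= f]
    subset_significance(fits, subset, alpha, seed = perm_seeds[f])
  })
  sig_ids <- names(final_ranks)[final_ranks < search$f_ns]
  sig_ids <- sig_ids[order(final_ranks[sig_ids])]
  if (length(sig_ids) > 0L) {
    list(features = sig_ids, registered = TRUE, ranks = final_ranks,
         fits = fits, trace = search$trace)
  } else {
    keep_n <- ceiling(p / 2)
    keep <- names(sort(final_ranks))[seq_len(keep_n)]
    list(features = keep, registered = FALSE, ranks = final_ranks,
         fits = fits, trace = search$trace)
  }
}

TIER_LETTERS <- c("A", "B", "C", "D", "E")

# Iterated rounds for one classifier. Returns tiers, final models, per-round
# traces, and fresh-bootstrap OOB accuracies of the full / S / S+A models.
.run_method <- function(x, method, boot, alpha, seed, max_rounds) {
  seeds <- .derive_seeds(seed, max_rounds + 5L)
  cur <- x
  discards <- list()   # chronological discard events
  traces <- list()
  converged <- FALSE
  signature <- character(0)
  n_rounds <- 0L
  for (round_i in seq_len(max_rounds)) {
    n_rounds <- round_i
    rs <- selection_round(cur, method = method, boot = boot, alpha = alpha,
                          seed = seeds[round_i])
    traces[[round_i]] <- dplyr::mutate(rs$trace, round = round_i,
                                       registered = rs$registered,
                                       .before = 1L)
    incoming <- colnames(cur$X)
    if (rs$registered && setequal(rs$features, incoming)) {
      signature <- rs$features
      converged <- TRUE
      break
    }
    if (!rs$registered && setequal(rs$features, incoming)) {
      # p = 1 and its single feature non-significant: nothing left to test
      discards <- c(discards, list(incoming))
      signature <- character(0)
      converged <- TRUE
      break
    }
    discards <- c(discards, list(setdiff(incoming, rs$features)))
    cur <- restrict_features(cur, rs$features)
  }
  if (!converged) {
    warning("selection for '", method, "' did not converge within ",
            max_rounds, " rounds; signature reported empty", call. = FALSE)
    signature <- character(0)
  }

  # reverse-chronological tier letters: last discard event -> A, previous ->
  # B, ... everything earlier than the 4th-from-last event lumped into E
  tiers <- stats::setNames(rep(NA_character_, ncol(x$X)), colnames(x$X))
  tiers[signature] <- "S"
  m <- length(discards)
  for (i in seq_len(m)) {
    letter_idx <- min(m - i + 1L, length(TIER_LETTERS))
    tiers[discards[[i]]] <- TIER_LETTERS[letter_idx]
  }
  tier_a <- names(tiers)[!is.na(tiers) & tiers == "A"]
  s_plus_a <- c(signature, tier_a)

  acc <- c(
    full = .oob_accuracy(x, colnames(x$X), method, boot, seeds[max_rounds + 1L]),
    S = .oob_accuracy(x, signature, method, boot, seeds[max_rounds + 2L]),
    SA = .oob_accuracy(x, s_plus_a, method, boot, seeds[max_rounds + 3L])
  )
  final_model <- if (length(signature) > 0L) {
    .fit_classifier(x$X[, signature, drop = FALSE], x$labels, x$positive,
                    method, seed = seeds[max_rounds + 4L])
  } else {
    NULL
  }
  final_model_sa <- if (length(s_plus_a) > 0L) {
    .fit_classifier(x$X[, s_plus_a, drop = FALSE], x$labels, x$positive,
                    method, seed = seeds[max_rounds + 5L])
  } else {
    NULL
  }
  list(
    method = method, signature = signature, tiers = tiers,
    n_rounds = n_rounds, converged = converged,
    trace = dplyr::bind_rows(traces), accuracy = acc,
    model_s = final_model, model_sa = final_model_sa
  )
}

#' Select a significant molecular signature by wrapper feature selection
#'
#' The main entry point: for each requested classifier (PLS-DA, Random
#' Forest, linear SVM), iterates selection rounds -- bootstrap resampling,
#' classifier-specific feature ranking aggregated by the median, and
#' half-interval search for the largest feature subset whose permutation in
#' the out-of-bag test sets does *not* significantly degrade balanced
#' accuracy -- restricting the table to the surviving features after each
#' round. The procedure converges when a round finds every remaining feature
#' significant (those features form the signature tier S) or when no feature
#' is left (empty signature). Features discarded along the way are binned
#' into tiers A (last round) through E (earliest rounds).
#'
#' Each classifier is run independently with its own sub-seed; a failure in
#' one classifier does not abort the others. For each classifier, the final
#' model is refitted once on all samples restricted to tier S, and balanced
#' accuracies of the full, S, and S+A models are estimated as mean
#' out-of-bag accuracy over `boot` fresh bootstrap resamples.
#'
#' @param data Data frame, one row per sample: a two-level class column,
#'   optionally a `sample_id` column, and numeric feature columns. A
#'   prepared [as_sig_data()] object is also accepted.
#' @param class Name of the class column (string).
#' @param positive_level Class level treated as positive for
#'   sensitivity/specificity; defaults to the lexicographically larger
#'   level.
#' @param methods Character vector, subset of `c("plsda", "rf", "svm")`.
#' @param boot Number of bootstrap resamples per round (default 50).
#' @param alpha Significance threshold on the non-exceedance proportion
#'   (default 0.05).
#' @param seed Integer master seed; fixes every source of randomness, so a
#'   rerun with the same configuration is bit-identical.
#' @param max_rounds Safety cap on selection rounds per classifier.
#' @return A `sig_selection` object with [tidy()][generics::tidy] (long
#'   feature x method tier table), [glance()][generics::glance] (one-row
#'   summary), `autoplot()`, and [write_tiers()] support. Components:
#'   `results` (per-method engine output incl. search traces and final
#'   models), `tiers` (long tibble), `accuracy` (tibble: method, model,
#'   n_features, balanced_accuracy), `config`.
#' @examples
#' \donttest{
#' d <- simulate_planted(n_per_class = 15, p = 20, d = 3, seed = 7)
#' fit <- select_signature(d, class = "class", methods = "plsda",
#'                         boot = 20, seed = 7)
#' tidy(fit)
#' glance(fit)
#' }
#' @export
select_signature <- function(data, class = "class", positive_level = NULL,
                             methods = c("plsda", "rf", "svm"), boot = 50L,
                             alpha = 0.05, seed = 1L, max_rounds = 20L) {
  stopifnot(boot >= 2L, alpha > 0, alpha < 1, max_rounds >= 1L)
  methods <- match.arg(methods, SIG_METHODS, several.ok = TRUE)
  x <- as_sig_data(data, class, positive_level)
  t0 <- proc.time()[["elapsed"]]
  seeds <- .derive_seeds(seed, length(methods))
  results <- vector("list", length(methods))
  names(results) <- methods
  for (i in seq_along(methods)) {
    results[[i]] <- tryCatch(
      .run_method(x, methods[i], boot, alpha, seeds[i], max_rounds),
      error = function(e) {
        warning("method '", methods[i], "' failed: ", conditionMessage(e),
                call. = FALSE)
        list(method = methods[i], signature = character(0),
             tiers = stats::setNames(rep(NA_character_, ncol(x$X)), colnames(x$X)),
             n_rounds = 0L, converged = FALSE, trace = tibble::tibble(),
             accuracy = c(full = NA_real_, S = NA_real_, SA = NA_real_),
             model_s = NULL, model_sa = NULL, error = conditionMessage(e))
      }
    )
  }

  tiers_long <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(feature_id = names(r$tiers), method = r$method,
                   tier = unname(r$tiers))
  }))
  acc_tbl <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(
      method = r$method,
      model = c("full", "S", "SA"),
      n_features = c(ncol(x$X), length(r$signature),
                     sum(!is.na(r$tiers) & r$tiers %in% c("S", "A"))),
      balanced_accuracy = unname(r$accuracy)
    )
  }))

  structure(
    list(
      results = results, tiers = tiers_long, accuracy = acc_tbl,
      feature_ids = colnames(x$X),
      config = list(class = if (is.character(class)) class else "class",
                    positive_level = x$positive, methods = methods,
                    boot = as.integer(boot), alpha = alpha,
                    seed = as.integer(seed), max_rounds = as.integer(max_rounds)),
      n = nrow(x$X), p = ncol(x$X),
      elapsed = proc.time()[["elapsed"]] - t0
    ),
    class = "sig_selection"
  )
}

#' Signatures of a selection result
#'
#' @param x A `sig_selection` object.
#' @param tier Tiers to include (default just `"S"`, the final signature).
#' @return Named list (per method) of feature-id vectors.
#' @export
signatures <- function(x, tier = "S") {
  stopifnot(inherits(x, "sig_selection"))
  lapply(x$results, function(r) {
    names(r$tiers)[!is.na(r$tiers) & r$tiers %in% tier]
  })
}

#' @export
print.sig_selection <- function(x, ...) {
  cat("Wrapper signature selection (", x$n, " samples x ", x$p,
      " features; boot = ", x$config$boot, ", alpha = ", x$config$alpha,
      ", seed = ", x$config$seed, ")\n", sep = "")
  for (r in x$results) {
    sig <- r$signature
    cat("  ", format(r$method, width = 6), " S = {",
        paste(sig, collapse = ", "), "} (", length(sig), " feature",
        if (length(sig) != 1L) "s", ", ", r$n_rounds, " round",
        if (r$n_rounds != 1L) "s", ")\n", sep = "")
  }
  cat("Balanced accuracies (mean OOB over fresh bootstraps):\n")
  print(tidyr::pivot_wider(x$accuracy, id_cols = "method",
                           names_from = "model",
                           values_from = "balanced_accuracy"), n = Inf)
  invisible(x)
}

#' @export
tidy.sig_selection <- function(x, ...) {
  dplyr::mutate(x$tiers,
                tier = factor(.data$tier, levels = c("S", TIER_LETTERS)))
}

#' @export
glance.sig_selection <- function(x, ...) {
  sigs <- signatures(x)
  tibble::tibble(
    n = x$n, p = x$p,
    boot = x$config$boot, alpha = x$config$alpha, seed = x$config$seed,
    n_methods = length(x$results),
    union_size = length(unique(unlist(sigs))),
    intersection_size = length(Reduce(intersect, sigs)),
    elapsed = x$elapsed
  )
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.sig_selection <- function(object, tiers = c("S", "A", "B", "C", "D"),
                                   ...) {
  td <- tidy(object)
  td <- dplyr::filter(td, !is.na(.data$tier), .data$tier %in% tiers)
  if (nrow(td) == 0L) {
    stop("no feature reached the requested tiers", call. = FALSE)
  }
  keep_feats <- unique(td$feature_id)
  td$feature_id <- factor(td$feature_id, levels = rev(keep_feats))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$method, y = .data$feature_id,
                                   fill = .data$tier)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1,
                               drop = FALSE, na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Tier",
                  title = "Signature tiers by classifier") +
    ggplot2::theme_minimal()
}
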