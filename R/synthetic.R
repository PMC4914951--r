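# Synthetic and semi-synthetic datasets with known ground truth, emulating
# log-scale omics intensity tables, plus the sensitivity/specificity harness
# for repeated selection runs.

#' Simulate a planted-signal intensity table
#'
#' Generates a balanced two-class samples-by-features table of Gaussian
#' log-intensity-like features: noise features are Normal(0, sd) in both
#' classes, while each informative (planted) feature is shifted upward by
#' `d * sd` in the `"case"` class (a standardised effect size d). An
#' optional equicorrelated block is induced through a shared latent factor:
#' block features are `sqrt(rho) * z + sqrt(1 - rho) * eps`, giving pairwise
#' correlation `rho` within the block.
#'
#' @param n_per_class Samples per class (classes `"case"` and `"control"`).
#' @param p Number of features (named `f0001`, `f0002`, ...).
#' @param n_informative Number of planted discriminant features (the first
#'   `n_informative` feature ids).
#' @param d Standardised effect size of the planted shift (>= 0; 0 plants
#'   nothing).
#' @param sd Within-class standard deviation.
#' @param rho Equicorrelation within the correlated block (0 <= rho < 1; 0
#'   disables the block).
#' @param rho_block Feature ids (or indices) of the equicorrelated block;
#'   defaults to the first `min(p, 10)` features when `rho > 0`.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return Tibble with `sample_id`, `class` and `p` feature columns, plus
#'   attributes `informative` (the planted feature ids) and
#'   `positive_level` (`"case"`, the shifted class). Use
#'   [planted_truth()] to read the ground truth back.
#' @examples
#' d <- simulate_planted(n_per_class = 10, p = 6, d = 2, seed = 1)
#' planted_truth(d)
#' @export
simulate_planted <- function(n_per_class = 20L, p = 100L, n_informative = 1L,
                             d = 3, sd = 1, rho = 0, rho_block = NULL,
                             seed = 1L) {
  stopifnot(n_per_class >= 2L, p >= 1L, d >= 0, sd > 0, rho >= 0, rho < 1,
            n_informative >= 0L, n_informative <= p)
  n <- 2L * n_per_class
  feature_ids <- sprintf("f%04d", seq_len(p))
  informative <- feature_ids[seq_len(n_informative)]
  classes <- rep(c("case", "control"), each = n_per_class)
  X <- .with_seed(seed, {
    M <- matrix(stats::rnorm(n * p, 0, sd), n, p,
                dimnames = list(paste0("s", seq_len(n)), feature_ids))
    if (rho > 0) {
      if (is.null(rho_block)) rho_block <- feature_ids[seq_len(min(p, 10L))]
      if (is.numeric(rho_block)) rho_block <- feature_ids[rho_block]
      z <- stats::rnorm(n, 0, sd)
      M[, rho_block] <- sqrt(rho) * z + sqrt(1 - rho) * M[, rho_block]
    }
    M[classes == "case", informative] <-
      M[classes == "case", informative, drop = FALSE] + d * sd
    M
  })
  out <- tibble::as_tibble(as.data.frame(X))
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(X), class = classes), out
  )
  attr(out, "informative") <- informative
  attr(out, "positive_level") <- "case"
  out
}

#' @rdname simulate_planted
#' @param data A table produced by [simulate_planted()] (or
#'   [spike_semisynthetic()], whose target plays the same role).
#' @export
planted_truth <- function(data) {
  truth <- attr(data, "informative")
  if (is.null(truth)) stop("no ground-truth attribute on this table", call. = FALSE)
  truth
}

#' Semi-synthetic spiking: a known multivariate-only target
#'
#' Builds a dataset with exactly one known discriminant feature kept below
#' univariate detectability, starting from any real-structured table:
#' (i) every feature significant by two-sided Wilcoxon rank-sum testing at a
#' Benjamini-Hochberg FDR of `fdr` is removed (the purge is iterated until
#' no survivor is significant); (ii) a surviving target feature is picked
#' (given or seeded-random); (iii) the largest multiplicative factor in
#' (1, `factor_max`] is found by bisection such that, after multiplying the
#' target's intensities in the `group` class, the target is *still* not
#' BH-significant at the FDR level; the factor is then applied. The result
#' is a table whose class signal is invisible to univariate testing but
#' available to multivariate classifiers.
#'
#' Note the factor multiplies the stored values as-is: on a log-scale table
#' this amounts to a power transform of the raw intensities.
#'
#' @inheritParams select_signature
#' @param fdr False discovery rate for the purge and the detectability bound
#'   (default 0.05).
#' @param target Feature id to spike; default: a seeded-random survivor.
#' @param group Class level whose intensities are multiplied; default: the
#'   positive level.
#' @param factor_max Upper bound of the factor search (default 10).
#' @return Tibble like `data` restricted to the surviving features with the
#'   target spiked; attributes `informative` (the target id), `factor`
#'   (value applied), `positive_level`.
#' @export
spike_semisynthetic <- function(data, class = "class", fdr = 0.05,
                                target = NULL, group = NULL,
                                factor_max = 10, positive_level = NULL,
                                seed = 1L) {
  stopifnot(fdr > 0, fdr < 1, factor_max > 1)
  x <- as_sig_data(data, class, positive_level)
  if (is.null(group)) group <- x$positive
  stopifnot(group %in% c(x$positive, x$negative))
  in_group <- x$labels == group

  wilcox_p <- function(M) {
    apply(M, 2L, function(v) {
      stats::wilcox.test(v[in_group], v[!in_group], exact = FALSE)$p.value
    })
  }
  # (i) iterated purge: drop BH-significant features until none remain
  M <- x$X
  repeat {
    if (ncol(M) < 10L) {
      stop("fewer than 10 features survive the significance purge", call. = FALSE)
    }
    padj <- stats::p.adjust(wilcox_p(M), method = "BH")
    if (all(padj > fdr)) break
    M <- M[, padj > fdr, drop = FALSE]
  }

  # (ii) target
  survivors <- colnames(M)
  if (is.null(target)) {
    target <- .with_seed(seed, sample(survivors, 1L))
  } else if (!target %in% survivors) {
    stop("target '", target, "' did not survive the purge", call. = FALSE)
  }

  # (iii) largest factor keeping the target BH-undetected, by bisection
  p_other <- wilcox_p(M[, setdiff(survivors, target), drop = FALSE])
  detected <- function(f) {
    v <- M[, target]
    v[in_group] <- v[in_group] * f
    pt <- stats::wilcox.test(v[in_group], v[!in_group], exact = FALSE)$p.value
    padj <- stats::p.adjust(c(pt, p_other), method = "BH")
    padj[1L] <= fdr
  }
  lo <- 1
  hi <- factor_max
  if (!detected(hi)) {
    factor_used <- hi
  } else {
    if (detected(1 + 1e-9)) {
      stop("no admissible factor > 1 for target '", target,
           "'; try a different target", call. = FALSE)
    }
    for (it in seq_len(50L)) {
      mid <- (lo + hi) / 2
      if (detected(mid)) hi <- mid else lo <- mid
    }
    factor_used <- lo  # largest verified-undetected factor
  }
  M[in_group, target] <- M[in_group, target] * factor_used

  out <- tibble::as_tibble(as.data.frame(M))
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(M), class = x$labels), out
  )
  attr(out, "informative") <- target
  attr(out, "factor") <- factor_used
  attr(out, "positive_level") <- x$positive
  out
}

#' Sensitivity and specificity of repeated selection runs
#'
#' Summarises how well repeated selection runs recover known ground-truth
#' features. A run's detected set is the union of its classifiers' tier-S
#' signatures. Sensitivity is the fraction of runs in which *every* truth
#' feature appears in the detected set; specificity is one minus the mean
#' fraction of non-truth features entering the detected set, averaged over
#' runs.
#'
#' @param runs List of `sig_selection` objects (from [select_signature()])
#'   or of character vectors of detected feature ids.
#' @param truth Character vector of ground-truth feature ids.
#' @param feature_ids All feature ids of the universe; inferred from the
#'   first `sig_selection` run when omitted.
#' @return Tibble with one row: `n_runs`, `sensitivity`, `specificity`.
#' @export
selection_sensitivity <- function(runs, truth, feature_ids = NULL) {
  stopifnot(length(runs) >= 1L)
  detected <- lapply(runs, function(r) {
    if (inherits(r, "sig_selection")) unique(unlist(signatures(r))) else as.character(r)
  })
  if (is.null(feature_ids)) {
    if (!inherits(runs[[1L]], "sig_selection")) {
      stop("feature_ids must be given when runs are plain id vectors",
           call. = FALSE)
    }
    feature_ids <- runs[[1L]]$feature_ids
  }
  truth <- as.character(truth)
  noise <- setdiff(feature_ids, truth)
  sens <- mean(vapply(detected, function(d) all(truth %in% d), logical(1)))
  false_frac <- vapply(detected, function(d) {
    if (length(noise) == 0L) 0 else length(intersect(d, noise)) / length(noise)
  }, numeric(1))
  tibble::tibble(
    n_runs = length(runs),
    sensitivity = sens,
    specificity = 1 - mean(false_frac)
  )
}
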