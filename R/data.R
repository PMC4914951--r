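#' Assemble and validate a samples-by-features dataset
#'
#' Converts a data frame holding one two-level class column plus numeric
#' feature columns into the validated internal representation used by all
#' selection, evaluation and baseline functions. Most users never call this
#' directly -- every user-facing function accepts the data frame and class
#' column and validates on entry -- but it is exported so that the checks can
#' be run in isolation.
#'
#' Validation enforces the contract shared by the whole package: all feature
#' cells numeric and finite (missing values are rejected, not imputed --
#' imputation is an upstream preprocessing concern), at least 4 samples,
#' exactly two class levels with at least 2 samples each, and unique sample
#' and feature identifiers. Constant (zero-variance) features are retained
#' but flagged: the wrapped classifiers tolerate them via a guarded scaling
#' denominator.
#'
#' @param data A data frame with one row per sample: a class column (see
#'   `class`), optionally a `sample_id` character column, and numeric feature
#'   columns (intensities, typically log-transformed upstream).
#' @param class Name of the two-level class column (string).
#' @param positive_level Which class level is "positive" for
#'   sensitivity/specificity orientation. Defaults to the lexicographically
#'   larger level so that the choice is deterministic without user input.
#' @param id Name of the sample identifier column; defaults to `"sample_id"`
#'   when present, otherwise row numbers are used.
#' @return An object of class `sig_data`: a list with `X` (numeric matrix,
#'   samples x features, dimnames set), `labels` (character vector),
#'   `positive` and `negative` (level strings), and `constant_features`
#'   (ids of zero-variance columns, possibly empty).
#' @examples
#' d <- simulate_planted(n_per_class = 5, p = 3, d = 0, seed = 1)
#' sd <- as_sig_data(d, class = "class")
#' dim(sd$X)
#' @export
as_sig_data <- function(data, class, positive_level = NULL, id = NULL) {
  if (inherits(data, "sig_data")) {
    return(data)
  }
  stopifnot(is.data.frame(data))
  if (!is.character(class) || length(class) != 1L || !class %in% names(data)) {
    stop("`class` must name a column of `data`.", call. = FALSE)
  }
  if (is.null(id) && "sample_id" %in% names(data)) id <- "sample_id"
  sample_ids <- if (!is.null(id)) {
    if (!id %in% names(data)) stop("id column '", id, "' not found.", call. = FALSE)
    as.character(data[[id]])
  } else {
    if (!is.null(rownames(data)) &&
        !identical(rownames(data), as.character(seq_len(nrow(data))))) {
      rownames(data)
    } else {
      paste0("s", seq_len(nrow(data)))
    }
  }
  labels <- as.character(data[[class]])
  feat_cols <- setdiff(names(data), c(class, id))
  is_num <- vapply(data[feat_cols], is.numeric, logical(1))
  if (any(!is_num)) {
    stop("non-numeric feature column(s): ",
         paste(feat_cols[!is_num], collapse = ", "),
         " (convert or drop them upstream)", call. = FALSE)
  }
  X <- as.matrix(data[feat_cols])
  storage.mode(X) <- "double"
  dimnames(X) <- list(sample_ids, feat_cols)
  new_sig_data(X, labels, positive_level)
}

#' @rdname as_sig_data
#' @param X Numeric matrix, samples in rows, features in columns, with
#'   dimnames.
#' @param labels Character vector of class labels, one per row of `X`.
#' @export
new_sig_data <- function(X, labels, positive_level = NULL) {
  stopifnot(is.matrix(X), is.numeric(X))
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(n))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  if (anyDuplicated(rownames(X))) stop("duplicated sample ids", call. = FALSE)
  if (anyDuplicated(colnames(X))) stop("duplicated feature ids", call. = FALSE)
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") != sample count (", n, ")",
         call. = FALSE)
  }
  if (n < 4L) stop("at least 4 samples are required (got ", n, ")", call. = FALSE)
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]
    j <- bad[1L, 2L]
    stop("non-finite value at sample '", rownames(X)[i], "' / feature '",
         colnames(X)[j],
         "': missing values must be imputed (or the feature removed) upstream",
         call. = FALSE)
  }
  labels <- as.character(labels)
  if (anyNA(labels)) stop("missing class labels", call. = FALSE)
  levs <- sort(unique(labels))
  if (length(levs) != 2L) {
    stop("class must have exactly 2 levels, got {",
         paste(levs, collapse = ", "), "}", call. = FALSE)
  }
  if (min(table(labels)) < 2L) {
    stop("each class needs >= 2 samples", call. = FALSE)
  }
  if (is.null(positive_level)) {
    positive_level <- levs[2L]  # lexicographically larger, deterministic
  } else {
    positive_level <- as.character(positive_level)
    if (!positive_level %in% levs) {
      stop("positive_level '", positive_level, "' is not a class level",
           call. = FALSE)
    }
  }
  sds <- apply(X, 2L, stats::sd)
  structure(
    list(
      X = X,
      labels = labels,
      positive = positive_level,
      negative = setdiff(levs, positive_level),
      constant_features = colnames(X)[sds == 0]
    ),
    class = "sig_data"
  )
}

#' @export
print.sig_data <- function(x, ...) {
  cat("<sig_data> ", nrow(x$X), " samples x ", ncol(x$X), " features; classes ",
      x$negative, "/", x$positive, " (positive: ", x$positive, ")\n", sep = "")
  invisible(x)
}

#' Restrict a dataset to an ordered subset of features
#'
#' Column selection in the order given; sample rows are untouched. This is
#' the restriction step applied between selection rounds, when the candidate
#' table is cut down to the features that survived the last round.
#'
#' @param x A `sig_data` object (see [as_sig_data()]).
#' @param keep Character vector of feature ids to keep, in the desired order.
#'   May be empty (yielding a 0-column table).
#' @return A `sig_data`-like object restricted to `keep`. With 0 or 1 kept
#'   features validation of the matrix shape is preserved.
#' @export
restrict_features <- function(x, keep) {
  stopifnot(inherits(x, "sig_data"))
  keep <- as.character(keep)
  unknown <- setdiff(keep, colnames(x$X))
  if (length(unknown) > 0L) {
    stop("unknown feature id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- x
  out$X <- x$X[, keep, drop = FALSE]
  out$constant_features <- intersect(x$constant_features, keep)
  out
}

#' Encode two-level class labels as a numeric response
#'
#' Maps the positive level to +0.5 and the other level to -0.5, the coding
#' used by the PLS-DA engine (the classifier regresses this numeric response
#' on the scaled intensities and thresholds predictions at 0).
#'
#' @inheritParams restrict_features
#' @return Numeric vector in \{-0.5, +0.5\}, one value per sample.
#' @examples
#' d <- simulate_planted(n_per_class = 3, p = 2, d = 0, seed = 1)
#' encode_labels(as_sig_data(d, "class"))
#' @export
encode_labels <- function(x) {
  stopifnot(inherits(x, "sig_data"))
  ifelse(x$labels == x$positive, 0.5, -0.5)
}
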