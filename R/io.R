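# Delimited-text input (peak tables, sample metadata) and run-report output.

.read_delim_auto <- function(path) {
  ext <- tolower(tools::file_ext(path))
  delim <- if (ext == "csv") "," else "\t"
  # base parser: correctly-rounded doubles, so written tables round-trip
  tibble::as_tibble(utils::read.delim(path, sep = delim, check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

#' Read a samples-by-features intensity table
#'
#' Reads a TSV or CSV (by extension) whose first column holds identifiers.
#' With `orientation = "samples_in_rows"` (default) rows are samples and the
#' remaining columns are features; with `"features_in_rows"` the file is the
#' transpose (one row per feature, one column per sample) and is transposed
#' on reading.
#'
#' @param path Path to a delimited text file.
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`.
#' @return Tibble with `sample_id` plus one numeric column per feature.
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_in_rows",
                                               "features_in_rows")) {
  orientation <- match.arg(orientation)
  raw <- .read_delim_auto(path)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicated identifiers in first column of ", path, call. = FALSE)
  }
  vals <- raw[-1L]
  not_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(not_num) > 0L) {
    stop("non-numeric cell(s) in column(s): ", paste(not_num, collapse = ", "),
         call. = FALSE)
  }
  M <- as.matrix(vals)
  rownames(M) <- ids
  if (orientation == "features_in_rows") M <- t(M)
  if (anyDuplicated(colnames(M))) {
    stop("duplicated feature ids in ", path, call. = FALSE)
  }
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(M)),
    tibble::as_tibble(as.data.frame(M))
  )
}

#' Write a samples-by-features table to delimited text
#'
#' Inverse of [read_feature_table()] (samples-in-rows orientation);
#' round-trips values and names exactly.
#'
#' @param data Tibble/data frame with a `sample_id` column plus numeric
#'   feature columns (a class column, if present, is written too).
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  # 17 significant digits guarantee exact double round-trips
  data <- dplyr::mutate(data, dplyr::across(
    dplyr::where(is.numeric), ~ sprintf("%.17g", .x)
  ))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    readr::write_csv(data, path, progress = FALSE)
  } else {
    readr::write_tsv(data, path, progress = FALSE)
  }
  invisible(path)
}

#' Read two-level class labels from a sample-metadata table
#'
#' Reads a metadata TSV/CSV whose first column holds sample ids, extracts
#' one class column, and (optionally) aligns the labels to a given sample
#' order, erroring on unmatched samples or more than two levels.
#'
#' @param path Path to the metadata file.
#' @param class_column Name of the class column.
#' @param sample_ids Optional character vector giving the sample order of
#'   the feature table; labels are re-aligned to it.
#' @return Tibble with `sample_id` and `class`.
#' @export
read_labels <- function(path, class_column, sample_ids = NULL) {
  meta <- .read_delim_auto(path)
  if (!class_column %in% names(meta)) {
    stop("class column '", class_column, "' not found in ", path, call. = FALSE)
  }
  ids <- as.character(meta[[1L]])
  labels <- as.character(meta[[class_column]])
  levs <- sort(unique(labels))
  if (length(levs) > 2L) {
    stop("class column '", class_column, "' has ", length(levs), " levels {",
         paste(levs, collapse = ", "), "}; exactly 2 are required",
         call. = FALSE)
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, ids)
    if (length(missing) > 0L) {
      stop("sample(s) absent from metadata: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    ord <- match(sample_ids, ids)
    ids <- ids[ord]
    labels <- labels[ord]
  }
  tibble::tibble(sample_id = ids, class = labels)
}

#' Write the tier table, accuracies and JSON run report
#'
#' Serialises a [select_signature()] result into three files under `dir`:
#' `tiers.tsv` (one row per feature, one tier column per classifier, `-`
#' when a feature received no tier), `accuracies.tsv` (balanced accuracy of
#' the full, S and S+A models per classifier, `na` when a signature is
#' empty), and `report.json` (configuration echo including the seed,
#' round-by-round search traces, tiers, accuracies, wall-clock and package
#' version -- enough provenance to re-run the analysis). The two TSV files
#' are deterministic functions of the inputs and seed.
#'
#' @param x A `sig_selection` object.
#' @param dir Output directory (created if needed).
#' @return Character vector of the three file paths, invisibly.
#' @export
write_tiers <- function(x, dir) {
  stopifnot(inherits(x, "sig_selection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiers_wide <- tidyr::pivot_wider(x$tiers, id_cols = "feature_id",
                                   names_from = "method",
                                   values_from = "tier")
  tiers_wide <- dplyr::mutate(tiers_wide, dplyr::across(
    -"feature_id", ~ ifelse(is.na(.x), "-", as.character(.x))
  ))
  f_tiers <- file.path(dir, "tiers.tsv")
  readr::write_tsv(tiers_wide, f_tiers, progress = FALSE)

  acc <- tidyr::pivot_wider(x$accuracy, id_cols = "method",
                            names_from = "model",
                            values_from = "balanced_accuracy")
  acc <- dplyr::mutate(acc, dplyr::across(
    -"method", ~ ifelse(is.na(.x), "na", sprintf("%.4f", .x))
  ))
  f_acc <- file.path(dir, "accuracies.tsv")
  readr::write_tsv(acc, f_acc, progress = FALSE)

  report <- list(
    package = "sigwrap",
    version = as.character(utils::packageVersion("sigwrap")),
    config = x$config,
    n_samples = x$n, n_features = x$p,
    elapsed_seconds = x$elapsed,
    methods = lapply(x$results, function(r) {
      list(
        signature = as.list(r$signature),
        n_rounds = r$n_rounds,
        converged = r$converged,
        accuracy = as.list(r$accuracy),
        trace = r$trace,
        error = r$error
      )
    }),
    tiers = tiers_wide
  )
  f_json <- file.path(dir, "report.json")
  jsonlite::write_json(report, f_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(tiers = f_tiers, accuracies = f_acc, report = f_json))
}
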