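#' Construct a dataset for additive modelling
#'
#' Bundles a numeric feature matrix with column names and a label vector.
#' In classification mode labels must be coded +1 (case) / -1 (control);
#' in regression mode the `labels` slot holds real-valued targets and the
#' classification invariants are suspended.
#'
#' @param features Numeric matrix (N rows, M feature columns) or data frame
#'   of numeric columns. All values must be finite.
#' @param labels Numeric vector of length N. For `mode = "classification"`
#'   every entry must be exactly `+1` or `-1`.
#' @param feature_names Optional character vector of M names; defaults to
#'   the column names of `features`.
#' @param mode `"classification"` or `"regression"`.
#'
#' @return An object of class `deepgam_dataset` with elements `features`,
#'   `feature_names`, `labels`, `n_positive` (classification only) and
#'   `mode`.
#' @export
deepgam_dataset <- function(features, labels,
                            feature_names = colnames(features),
                            mode = c("classification", "regression")) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 1L || ncol(features) < 1L) {
    stop("dataset needs at least one row and one feature column", call. = FALSE)
  }
  if (!all(is.finite(features))) {
    bad <- which(!is.finite(features), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature value at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  labels <- as.numeric(labels)
  if (length(labels) != nrow(features)) {
    stop("labels length must equal the number of feature rows", call. = FALSE)
  }
  if (mode == "classification" && !all(labels %in% c(-1, 1))) {
    stop("classification labels must be exactly +1 or -1", call. = FALSE)
  }
  if (mode == "regression" && !all(is.finite(labels))) {
    stop("regression targets must be finite", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- paste0("x", seq_len(ncol(features)))
  }
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(features)) {
    stop("feature_names length must equal the number of columns", call. = FALSE)
  }
  colnames(features) <- feature_names
  structure(
    list(
      features = features,
      feature_names = feature_names,
      labels = labels,
      n_positive = if (mode == "classification") sum(labels == 1) else NA_integer_,
      mode = mode
    ),
    class = "deepgam_dataset"
  )
}

#' @export
print.deepgam_dataset <- function(x, ...) {
  cat(sprintf("<deepgam_dataset> %d rows x %d features (%s)\n",
              nrow(x$features), ncol(x$features), x$mode))
  if (x$mode == "classification") {
    cat(sprintf("  positives: %d (%.1f%%)\n", x$n_positive,
                100 * x$n_positive / nrow(x$features)))
  }
  invisible(x)
}

#' @export
dim.deepgam_dataset <- function(x) dim(x$features)

#' Subset the rows of a dataset
#'
#' @param data A [deepgam_dataset()].
#' @param rows Integer row indices to keep.
#' @return A `deepgam_dataset` restricted to `rows`.
#' @export
dataset_rows <- function(data, rows) {
  stopifnot(inherits(data, "deepgam_dataset"))
  deepgam_dataset(data$features[rows, , drop = FALSE],
                  data$labels[rows],
                  feature_names = data$feature_names,
                  mode = data$mode)
}

#' Restrict a dataset to a subset of feature columns
#'
#' @param data A [deepgam_dataset()].
#' @param cols Integer column indices (or feature names) to keep.
#' @return A `deepgam_dataset` with only the requested columns.
#' @export
dataset_cols <- function(data, cols) {
  stopifnot(inherits(data, "deepgam_dataset"))
  if (is.character(cols)) cols <- match(cols, data$feature_names)
  if (anyNA(cols) || any(cols < 1L) || any(cols > ncol(data$features))) {
    stop("invalid feature columns requested", call. = FALSE)
  }
  deepgam_dataset(data$features[, cols, drop = FALSE],
                  data$labels,
                  feature_names = data$feature_names[cols],
                  mode = data$mode)
}

#' Load a delimited table as a classification dataset
#'
#' Reads a comma-separated file with a header row, maps the target column
#' to +1 / -1 labels and returns the remaining numeric columns as features.
#'
#' @param path Path to a CSV file (header row required, "." decimal).
#' @param target_column Name of the target column.
#' @param positive_label Raw target value mapped to +1; every other value
#'   maps to -1.
#' @param impute `"none"` (default: any missing or non-numeric cell is an
#'   error naming its row and column) or `"median"` (missing feature cells
#'   are replaced by the column median).
#'
#' @return A [deepgam_dataset()] in classification mode.
#' @export
load_table <- function(path, target_column, positive_label = 1,
                       impute = c("none", "median")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!target_column %in% names(df)) {
    stop(sprintf("target column '%s' not found in %s", target_column, path),
         call. = FALSE)
  }
  target_raw <- df[[target_column]]
  feat <- df[setdiff(names(df), target_column)]
  for (nm in names(feat)) {
    col <- feat[[nm]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value in column '%s', row %d", nm, bad[1L]),
             call. = FALSE)
      }
      col <- num
    }
    if (anyNA(col)) {
      if (impute == "median") {
        col[is.na(col)] <- stats::median(col, na.rm = TRUE)
      } else {
        stop(sprintf("missing value in column '%s', row %d",
                     nm, which(is.na(col))[1L]), call. = FALSE)
      }
    }
    feat[[nm]] <- col
  }
  labels <- ifelse(target_raw == positive_label, 1, -1)
  deepgam_dataset(as.matrix(feat), labels, feature_names = names(feat))
}

#' Write a dataset to CSV
#'
#' The inverse of [load_table()]: feature columns plus a target column.
#' Values are written at full precision so that a write/reload round trip
#' reproduces them.
#'
#' @param data A [deepgam_dataset()].
#' @param path Output CSV path.
#' @param target_column Name for the label column.
#' @return Invisibly, `path`.
#' @export
write_table <- function(data, path, target_column = "target") {
  stopifnot(inherits(data, "deepgam_dataset"))
  if (target_column %in% data$feature_names) {
    stop("target_column clashes with a feature name", call. = FALSE)
  }
  df <- as.data.frame(data$features, check.names = FALSE)
  df[[target_column]] <- data$labels
  # format at 17 significant digits so doubles survive the text round trip
  out <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L)
  lines <- c(paste(names(df), collapse = ","),
             apply(out, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
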