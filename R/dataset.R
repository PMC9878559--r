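#' Conformation dataset
#'
#' The package's central container: one row per MD-frame protein
#' conformation, one column per physico-chemical descriptor (MOE-style,
#' unitless), plus a binary label marking the minority "binding" class
#' (1 = binding, 0 = non-binding). Row order is MD frame order and is
#' treated as meaningful: the recurrence-based feature scorer reads each
#' descriptor column as a frame-ordered series, so I/O and projection
#' never reorder rows.
#'
#' @param features Numeric matrix or data frame, n conformations x d
#'   descriptors. Column names are used as feature names when
#'   `feature_names` is missing.
#' @param labels Vector of 0/1 labels, length n; 1 marks binding
#'   (minority) conformations.
#' @param name Text label for the dataset (e.g. a protein identifier).
#' @param feature_names Optional character vector of d unique descriptor
#'   names; defaults to the column names of `features`.
#'
#' @return An object of class `conformation_dataset`: a list with elements
#'   `name`, `features` (numeric matrix with column names),
#'   `feature_names`, and `labels` (integer vector).
#'
#' @examples
#' ds <- conformation_dataset(matrix(rnorm(20), 10, 2,
#'                                   dimnames = list(NULL, c("a", "b"))),
#'                            labels = rep(c(0, 1), 5))
#' ds
#' @export
conformation_dataset <- function(features, labels, name = "dataset",
                                 feature_names = NULL) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features))
    stop_("`features` must be a numeric matrix or all-numeric data frame")
  n <- nrow(features)
  d <- ncol(features)
  if (n < 2L) stop_("a conformation dataset needs at least 2 rows (got %d)", n)
  if (d < 1L) stop_("a conformation dataset needs at least 1 feature column")
  if (anyNA(features) || any(!is.finite(features)))
    stop_("`features` contains missing or non-finite values")
  if (is.null(feature_names)) feature_names <- colnames(features)
  if (is.null(feature_names))
    feature_names <- sprintf("feature_%02d", seq_len(d))
  feature_names <- as.character(feature_names)
  if (length(feature_names) != d)
    stop_("`feature_names` has length %d but there are %d feature columns",
          length(feature_names), d)
  if (anyDuplicated(feature_names))
    stop_("feature names must be unique (duplicated: %s)",
          paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  if (length(labels) != n)
    stop_("`labels` has length %d but there are %d rows", length(labels), n)
  labels <- check_binary_vector(labels, "labels")
  colnames(features) <- feature_names
  structure(
    list(name = as.character(name)[1L], features = features,
         feature_names = feature_names, labels = labels),
    class = "conformation_dataset"
  )
}

#' @export
print.conformation_dataset <- function(x, ...) {
  n1 <- sum(x$labels == 1L)
  cat(sprintf(
    "<conformation_dataset> %s: %d conformations x %d descriptors\n",
    x$name, nrow(x$features), ncol(x$features)))
  cat(sprintf("  binding (class 1): %d   non-binding (class 0): %d   (%.1f%% binding)\n",
              n1, sum(x$labels == 0L), 100 * n1 / length(x$labels)))
  invisible(x)
}

#' @export
summary.conformation_dataset <- function(object, ...) {
  print(object)
  cat("  descriptor ranges:\n")
  rng <- t(apply(object$features, 2, range))
  print(utils::head(data.frame(feature = object$feature_names,
                               min = rng[, 1], max = rng[, 2],
                               row.names = NULL), 10))
  if (length(object$feature_names) > 10) cat("  ...\n")
  invisible(object)
}

#' @export
dim.conformation_dataset <- function(x) dim(x$features)

# both classes present, as required by anything that trains or scores
check_two_classes <- function(ds, what = "this operation") {
  tab <- table(factor(ds$labels, levels = c(0, 1)))
  if (any(tab == 0L))
    stop_("%s requires both classes; dataset '%s' has %d binding and %d non-binding rows",
          what, ds$name, tab[["1"]], tab[["0"]])
  invisible(ds)
}

#' Read a conformation dataset from CSV
#'
#' Expects a comma-separated file with a header row: one numeric column per
#' descriptor plus a 0/1 label column. An optional `frame` column is treated
#' as a row index and dropped. File row order (MD frame order) is preserved.
#' Both descriptor dialects seen for GPCR tables (50 columns, or 51 with
#' `pro_pl_seq`) load identically; the column count is simply whatever the
#' file carries.
#'
#' @param path Path to a CSV file with header.
#' @param label_column Name of the 0/1 label column (default `"label"`).
#' @param name Dataset name; defaults to the file name without extension.
#' @return A [conformation_dataset()].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path, label_column = "label", name = NULL) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (!label_column %in% names(df))
    stop_("label column '%s' not found in %s (columns: %s)",
          label_column, path, paste(utils::head(names(df), 8), collapse = ", "))
  df[["frame"]] <- NULL
  lab <- df[[label_column]]
  df[[label_column]] <- NULL
  if (ncol(df) < 1L) stop_("no descriptor columns in %s", path)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      stop_("non-numeric value in column '%s', row %d of %s",
            names(df)[j], if (is.na(bad)) 1L else bad, path)
    }
    if (anyNA(col))
      stop_("missing value in column '%s', row %d of %s",
            names(df)[j], which(is.na(col))[1], path)
  }
  if (anyNA(lab) || !all(lab %in% c(0, 1)))
    stop_("label column '%s' in %s must contain only 0/1, no missing values",
          label_column, path)
  if (length(unique(lab)) < 2L)
    stop_("label column '%s' in %s contains a single class; both binding and non-binding rows are required",
          label_column, path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  conformation_dataset(as.matrix(df), lab, name = name)
}

#' Write a conformation dataset to CSV
#'
#' Inverse of [read_dataset()]: the header is the feature names followed by
#' the label column, rows are written in frame order, and
#' `read_dataset(write_dataset(ds))` reproduces the dataset exactly (full
#' double precision is kept via 17 significant digits).
#'
#' @param ds A [conformation_dataset()].
#' @param path Output file path.
#' @param label_column Name for the label column (default `"label"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, label_column = "label") {
  stopifnot(inherits(ds, "conformation_dataset"))
  if (label_column %in% ds$feature_names)
    stop_("label column name '%s' collides with a feature name", label_column)
  df <- as.data.frame(ds$features, check.names = FALSE)
  df[[label_column]] <- ds$labels
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_("directory does not exist: %s", dir)
  # format() at 17 digits makes the text round-trip bit-exact for doubles
  num <- vapply(seq_len(ncol(ds$features)), function(j)
    format(ds$features[, j], digits = 17, trim = TRUE, scientific = NA),
    character(nrow(ds$features)))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1L)
  out <- cbind(num, as.character(ds$labels))
  lines <- c(paste(c(ds$feature_names, label_column), collapse = ","),
             apply(out, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a dataset to a subset of descriptors
#'
#' Used after consensus feature selection to build the projected dataset the
#' second-stage classifiers train on. Column order follows `keep`; labels
#' and row (frame) order are untouched.
#'
#' @param ds A [conformation_dataset()].
#' @param keep Character vector of feature names to retain (non-empty,
#'   all present in `ds`).
#' @return A [conformation_dataset()] with `length(keep)` columns.
#' @export
project_features <- function(ds, keep) {
  stopifnot(inherits(ds, "conformation_dataset"))
  keep <- as.character(keep)
  if (length(keep) == 0L) stop_("`keep` must name at least one feature")
  unknown <- setdiff(keep, ds$feature_names)
  if (length(unknown))
    stop_("unknown feature name(s): %s", paste(unknown, collapse = ", "))
  conformation_dataset(ds$features[, keep, drop = FALSE], ds$labels,
                       name = ds$name, feature_names = keep)
}
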