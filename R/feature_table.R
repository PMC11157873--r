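#' Construct a feature table
#'
#' A feature table is the common currency of every stage of the harmonization
#' pipeline: one row per ROI sample, one column per radiomic feature, plus a
#' scanner-manufacturer batch label and a binary texture-class label per
#' sample. It is stored as a plain `data.frame` with leading columns
#' `sample_id`, `batch`, `class`, followed by one numeric column per feature,
#' so it serializes naturally to CSV.
#'
#' @param values numeric matrix, samples in rows and features in columns.
#'   Column names are used as feature names when present.
#' @param batch per-sample batch labels (coerced to factor).
#' @param class per-sample class labels, coded 0 (rubber-like texture) or
#'   1 (ABS-like texture).
#' @param sample_id optional per-sample identifiers; defaults to `s1, s2, ...`.
#' @param feature_names optional feature names overriding `colnames(values)`.
#'
#' @return a `data.frame` of class `"feature_table"`.
#' @export
feature_table <- function(values, batch, class, sample_id = NULL,
                          feature_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  n <- nrow(values)
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names)) {
    feature_names <- sprintf("feat_%03d", seq_len(ncol(values)))
  }
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length must match ncol(values)")
  }
  if (any(!is.finite(values))) stop("feature values must be finite (no NA/Inf)")
  if (length(batch) != n || length(class) != n) {
    stop("'batch' and 'class' must have one entry per sample")
  }
  class <- as.integer(class)
  if (!all(class %in% c(0L, 1L))) stop("'class' labels must be 0 or 1")
  if (is.null(sample_id)) sample_id <- sprintf("s%d", seq_len(n))
  reserved <- c("sample_id", "batch", "class")
  if (any(feature_names %in% reserved)) {
    stop("feature names may not collide with 'sample_id', 'batch' or 'class'")
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    batch = factor(batch),
                    class = class,
                    stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.data.frame(values)
  names(vals) <- feature_names
  out <- cbind(out, vals)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features; batches: %s\n",
              nrow(x), length(feature_names(x)),
              paste(levels(x$batch), collapse = ", ")))
  invisible(x)
}

#' Extract the numeric sample-by-feature matrix of a feature table
#' @param table a `feature_table`.
#' @return numeric matrix with sample ids as row names.
#' @export
feature_matrix <- function(table) {
  stopifnot(is_feature_table(table))
  m <- as.matrix(table[, feature_names(table), drop = FALSE])
  rownames(m) <- table$sample_id
  m
}

#' Feature names of a feature table
#' @param table a `feature_table`.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("sample_id", "batch", "class"))
}

#' Test whether an object is a feature table
#' @param x object.
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

# Replace the feature values of a table, keeping labels and sample order.
set_feature_values <- function(table, values) {
  stopifnot(is_feature_table(table),
            nrow(values) == nrow(table),
            ncol(values) == length(feature_names(table)))
  table[, feature_names(table)] <- values
  table
}

#' Validate a feature table ahead of harmonization
#'
#' Checks the invariants harmonization relies on: at least two batches and
#' at least two samples in every batch.
#'
#' @param table a `feature_table`.
#' @return invisibly `TRUE`; otherwise an error.
#' @export
validate_for_harmonization <- function(table) {
  stopifnot(is_feature_table(table))
  counts <- table(table$batch)
  if (length(counts) < 2) stop("harmonization needs at least 2 batches")
  if (any(counts < 2)) {
    stop("every batch needs at least 2 samples; offending batch: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a feature table to CSV
#'
#' Layout: columns `sample_id,batch,class`, then one column per feature;
#' UTF-8, '.' decimal, header row mandatory.
#'
#' @param table a `feature_table`.
#' @param path output file path.
#' @export
write_feature_csv <- function(table, path) {
  stopifnot(is_feature_table(table))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table from CSV
#' @param path CSV file written by [write_feature_csv()] or following the same
#'   layout.
#' @return a `feature_table`.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "batch", "class")
  if (!all(need %in% names(df))) {
    stop("feature CSV must contain columns: ", paste(need, collapse = ", "))
  }
  feats <- setdiff(names(df), need)
  feature_table(as.matrix(df[, feats, drop = FALSE]),
                batch = df$batch, class = df$class,
                sample_id = df$sample_id, feature_names = feats)
}
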