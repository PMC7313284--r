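# Reading feature tables / label files and the [-1, 1] range scaler.

#' Read a per-window feature table
#'
#' Reads a plain-text feature table with one fixed-length window per row:
#' either whitespace-delimited (the layout of UCI-HAR style `X_train.txt`
#' files) or comma-separated. For CSV input a non-numeric first row is
#' treated as a header and skipped. Rows are returned in file order; no
#' reordering or scaling is applied.
#'
#' @param path Path to the text file.
#' @param dialect `"whitespace"` (default) or `"csv"`.
#' @return A numeric matrix with one row per window.
#' @export
read_feature_table <- function(path, dialect = c("whitespace", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty feature table: %s", path))
  split_fun <- if (dialect == "whitespace") {
    function(l) strsplit(trimws(l), "[[:space:]]+")[[1]]
  } else {
    function(l) trimws(strsplit(l, ",", fixed = TRUE)[[1]])
  }
  cells <- lapply(lines, split_fun)
  start <- 1L
  if (dialect == "csv") {
    first <- suppressWarnings(as.numeric(cells[[1]]))
    if (anyNA(first)) start <- 2L  # header row
    if (start > length(cells)) stop(sprintf("no data rows in %s", path))
  }
  cells <- cells[start:length(cells)]
  p <- length(cells[[1]])
  widths <- lengths(cells)
  if (any(widths != p)) {
    bad <- which(widths != p)[1]
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad + start - 1L, widths[bad], p))
  }
  vals <- suppressWarnings(vapply(cells, as.numeric, numeric(p)))
  if (anyNA(vals)) {
    if (p == 1L) vals <- matrix(vals, nrow = 1L)
    bad <- which(apply(is.na(vals), 2L, any))[1]
    stop(sprintf("non-numeric value in %s at line %d", path, bad + start - 1L))
  }
  if (p == 1L) matrix(vals, ncol = 1L) else t(vals)
}

#' Read an activity label file
#'
#' Reads one integer label per line (UCI-HAR style `y_train.txt` layout).
#' Labels are 1-based class indices.
#'
#' @param path Path to the text file.
#' @param n_classes Number of classes; inferred as `max(labels)` when `NULL`.
#' @return Integer vector of labels with attribute `n_classes`.
#' @export
read_label_file <- function(path, n_classes = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("empty label file: %s", path))
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals) || any(vals != floor(vals))) {
    bad <- which(is.na(vals) | vals != floor(vals))[1]
    stop(sprintf("non-integer label in %s at line %d", path, bad))
  }
  labels <- as.integer(vals)
  if (any(labels < 1L)) stop("labels must be 1-based (found a label < 1)")
  if (is.null(n_classes)) n_classes <- max(labels)
  labels <- check_labels(labels, n_classes = n_classes)
  attr(labels, "n_classes") <- as.integer(n_classes)
  labels
}

#' Fit a per-feature [-1, 1] range scaler
#'
#' Stores the column-wise minimum and maximum of the training features.
#' [apply_normalizer()] then maps each feature affinely so the training
#' range becomes exactly \eqn{[-1, 1]}.
#'
#' @param x Numeric matrix of training features (rows = windows).
#' @return An object of class `"range_normalizer"`.
#' @seealso [apply_normalizer()]
#' @export
fit_normalizer <- function(x) {
  x <- as_feature_matrix(x)
  structure(
    list(min = apply(x, 2L, min), max = apply(x, 2L, max), p = ncol(x)),
    class = "range_normalizer"
  )
}

#' Apply a fitted range scaler
#'
#' Maps each feature as \eqn{x' = 2 (x - min) / (max - min) - 1} using the
#' training extrema. Values outside the training range are not clipped, so
#' test data may fall outside \eqn{[-1, 1]}; a feature that was constant in
#' training maps to 0.
#'
#' @param norm A `"range_normalizer"` from [fit_normalizer()].
#' @param x Numeric matrix with the same number of columns as the training data.
#' @return The scaled matrix.
#' @export
apply_normalizer <- function(norm, x) {
  stopifnot(inherits(norm, "range_normalizer"))
  x <- as_feature_matrix(x)
  if (ncol(x) != norm$p) {
    stop(sprintf("feature count mismatch: normalizer fitted on %d columns, input has %d",
                 norm$p, ncol(x)))
  }
  rng <- norm$max - norm$min
  out <- sweep(x, 2L, norm$min, "-")
  nonconst <- rng > 0
  out[, nonconst] <- 2 * sweep(out[, nonconst, drop = FALSE], 2L,
                               rng[nonconst], "/") - 1
  out[, !nonconst] <- 0
  out
}
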