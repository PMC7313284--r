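# Internal helpers shared across the package.

#' @keywords internal
round_half_away <- function(x) {
  # round() in R rounds half to even; class costs use half away from zero
  sign(x) * floor(abs(x) + 0.5)
}

#' Run an expression under a fixed RNG seed, restoring global RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @keywords internal
as_feature_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix of windows x features", arg))
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg))
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite entries", arg))
  }
  x
}

#' @keywords internal
check_labels <- function(labels, n_obs = NULL, n_classes = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels contain NA")
  if (any(labels < 1L)) stop("labels must be 1-based positive integers")
  if (!is.null(n_obs) && length(labels) != n_obs) {
    stop(sprintf("label length (%d) does not match number of rows (%d)",
                 length(labels), n_obs))
  }
  if (!is.null(n_classes) && any(labels > n_classes)) {
    stop(sprintf("labels exceed the declared class count N = %d", n_classes))
  }
  labels
}

#' Split row indices into contiguous per-subject runs.
#' @keywords internal
subject_runs <- function(subjects, n) {
  if (is.null(subjects)) return(list(seq_len(n)))
  if (length(subjects) != n) stop("subject ids must have one entry per row")
  codes <- as.integer(factor(subjects, levels = unique(subjects)))
  grp <- cumsum(c(TRUE, diff(codes) != 0L))
  unname(split(seq_len(n), grp))
}

#' Stratified fold assignment: per class, round-robin after a seeded shuffle.
#' @keywords internal
stratified_folds <- function(labels, folds, seed = NULL) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be at least 2")
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("every class needs at least 2 samples for stratified cross-validation")
  }
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}
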