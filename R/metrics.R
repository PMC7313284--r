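# Confusion matrices and macro-averaged evaluation metrics.

#' Confusion matrix of true vs predicted activities
#'
#' @param true,pred Integer label vectors of equal length, values in 1..N.
#' @param n_classes Number of classes N; inferred as the max observed label
#'   when `NULL`.
#' @return N x N integer matrix of counts; rows are true classes, columns
#'   predicted classes. Class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(true, pred, n_classes = NULL) {
  if (length(true) != length(pred)) stop("true and pred must have equal length")
  if (is.null(n_classes)) n_classes <- max(c(true, pred))
  n_classes <- as.integer(n_classes)
  true <- check_labels(true, n_classes = n_classes)
  pred <- check_labels(pred, n_obs = length(true), n_classes = n_classes)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = seq_len(n_classes), pred = seq_len(n_classes)))
  for (t in seq_along(true)) cm[true[t], pred[t]] <- cm[true[t], pred[t]] + 1L
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Row-percentage view of a confusion matrix
#'
#' Expresses each row (true class) as percentages of its total, the
#' convention used to report per-activity confusion tables. Rows with no
#' true instances are returned as `NA` rather than silently zero.
#'
#' @param cm A confusion matrix of counts.
#' @param digits Decimal places for display rounding (half away from zero);
#'   `NULL` keeps full precision.
#' @return Numeric matrix of row percentages.
#' @export
row_percentages <- function(cm, digits = NULL) {
  cm <- unclass(cm)
  totals <- rowSums(cm)
  out <- 100 * cm / ifelse(totals == 0, NA_real_, totals)
  if (!is.null(digits)) out <- round_half_away(out * 10^digits) / 10^digits
  out
}

#' Macro-averaged classification report
#'
#' Per-class recall (row-wise diagonal fraction) and precision (column-wise),
#' their unweighted means \eqn{\bar R} and \eqn{\bar P} over classes, the
#' F-measure as the harmonic mean \eqn{\bar F = 2 \bar P \bar R /
#' (\bar P + \bar R)}, and overall accuracy (trace over total). All values
#' are percentages computed from unrounded internals.
#'
#' @param cm A confusion matrix of counts; every class needs at least one
#'   true instance.
#' @return An object of class `"metrics_report"`: `recall`, `precision`,
#'   `f1` (per class, %), `macro_recall`, `macro_precision`, `f_measure`,
#'   `accuracy` (%).
#' @export
classification_report <- function(cm) {
  cm <- unclass(cm)
  row_tot <- rowSums(cm)
  if (any(row_tot == 0)) {
    stop(sprintf("class %d has no true instances", which(row_tot == 0)[1]))
  }
  col_tot <- colSums(cm)
  diagc <- diag(cm)
  recall <- 100 * diagc / row_tot
  precision <- 100 * ifelse(col_tot == 0, 0, diagc / col_tot)
  f1 <- ifelse(recall + precision == 0, 0,
               2 * precision * recall / (precision + recall))
  macro_r <- mean(recall)
  macro_p <- mean(precision)
  structure(
    list(recall = recall, precision = precision, f1 = f1,
         macro_recall = macro_r, macro_precision = macro_p,
         f_measure = 2 * macro_p * macro_r / (macro_p + macro_r),
         accuracy = 100 * sum(diagc) / sum(cm)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  disp <- function(v) round_half_away(v * 10) / 10
  cat("Per-class (%):\n")
  print(data.frame(recall = disp(x$recall), precision = disp(x$precision),
                   f1 = disp(x$f1)))
  cat(sprintf("Averaged: recall %.1f, precision %.1f, F-measure %.1f, accuracy %.1f\n",
              disp(x$macro_recall), disp(x$macro_precision),
              disp(x$f_measure), disp(x$accuracy)))
  invisible(x)
}

#' Write an evaluation report to CSV files
#'
#' Writes the counts matrix, the row-percentage matrix, and per-class plus
#' averaged metrics next to each other under a common path prefix.
#'
#' @param cm A confusion matrix of counts.
#' @param prefix Output path prefix; files `<prefix>_counts.csv`,
#'   `<prefix>_row_percent.csv`, `<prefix>_metrics.csv` are written.
#' @return Invisibly, the metrics report.
#' @export
write_evaluation <- function(cm, prefix) {
  rep <- classification_report(cm)
  utils::write.csv(unclass(cm), paste0(prefix, "_counts.csv"))
  utils::write.csv(row_percentages(cm, digits = 1), paste0(prefix, "_row_percent.csv"))
  per <- data.frame(class = seq_along(rep$recall), recall = rep$recall,
                    precision = rep$precision, f1 = rep$f1)
  avg <- data.frame(class = c("macro", "accuracy"),
                    recall = c(rep$macro_recall, NA),
                    precision = c(rep$macro_precision, NA),
                    f1 = c(rep$f_measure, rep$accuracy))
  utils::write.csv(rbind(per, avg), paste0(prefix, "_metrics.csv"), row.names = FALSE)
  invisible(rep)
}
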