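# Confusion-matrix metrics for binary classification, reported as
# percentages: accuracy, precision, recall (sensitivity), specificity and
# F1-score.

#' Compute classification metrics
#'
#' Confusion counts treat label 1 (ASD) as the positive class.  All five
#' metrics are percentages.  When a denominator is zero (e.g. no positive
#' predictions for precision) the metric is reported as 0 with a warning.
#'
#' @param y_true integer vector of true labels (0/1).
#' @param y_pred integer vector of predicted labels (0/1).
#' @return a `metrics_report` with confusion counts and the five metrics.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length")
  if (!all(c(y_true, y_pred) %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  TP <- sum(y_true == 1 & y_pred == 1)
  TN <- sum(y_true == 0 & y_pred == 0)
  FP <- sum(y_true == 0 & y_pred == 1)
  FN <- sum(y_true == 1 & y_pred == 0)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as 0", what))
      return(0)
    }
    100 * num / den
  }
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 accuracy = safe(TP + TN, TP + TN + FP + FN, "accuracy"),
                 precision = safe(TP, TP + FP, "precision"),
                 recall = safe(TP, TP + FN, "recall"),
                 specificity = safe(TN, TN + FP, "specificity"),
                 f1 = safe(2 * TP, 2 * TP + FP + FN, "F1-score")),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("confusion: TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  recall %.2f%%  specificity %.2f%%  F1 %.2f%%\n",
              x$accuracy, x$precision, x$recall, x$specificity, x$f1))
  invisible(x)
}

#' Aggregate per-fold metric reports
#'
#' Mean of each metric across folds, summed confusion counts, and the
#' sample variance of fold accuracies.
#'
#' @param per_fold list of `metrics_report` objects.
#' @return a `metrics_aggregate`.
#' @export
aggregate_metrics <- function(per_fold) {
  nm <- c("accuracy", "precision", "recall", "specificity", "f1")
  agg <- lapply(nm, function(m) mean(vapply(per_fold, `[[`, 0, m)))
  names(agg) <- nm
  counts <- lapply(c("TP", "TN", "FP", "FN"), function(m)
    sum(vapply(per_fold, `[[`, 0L, m)))
  names(counts) <- c("TP", "TN", "FP", "FN")
  acc <- vapply(per_fold, `[[`, 0, "accuracy")
  structure(c(counts, agg,
              list(accuracy_variance = if (length(acc) > 1) stats::var(acc)
                                       else 0,
                   per_fold = per_fold)),
            class = c("metrics_aggregate", "metrics_report"))
}

#' @export
print.metrics_aggregate <- function(x, ...) {
  cat(sprintf("%d folds; mean accuracy %.2f%% (variance %.2f)\n",
              length(x$per_fold), x$accuracy, x$accuracy_variance))
  cat(sprintf("mean precision %.2f%%  recall %.2f%%  specificity %.2f%%  F1 %.2f%%\n",
              x$precision, x$recall, x$specificity, x$f1))
  invisible(x)
}

#' Write a metrics report to CSV and JSON
#'
#' @param report a `metrics_report` or aggregate.
#' @param stem output path stem; `.csv` and `.json` are appended.
#' @return invisibly, the two paths.
#' @export
write_metrics <- function(report, stem) {
  nm <- c("TP", "TN", "FP", "FN", "accuracy", "precision", "recall",
          "specificity", "f1")
  row <- as.data.frame(report[nm])
  utils::write.csv(row, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(report[intersect(names(report),
                                        c(nm, "accuracy_variance"))],
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(csv = paste0(stem, ".csv"), json = paste0(stem, ".json")))
}
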