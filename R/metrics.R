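#' Naive majority-class accuracy baseline
#'
#' The accuracy achieved by always predicting the majority class — the gate
#' every accepted Monte-Carlo model must beat. With 103 positives among 3561
#' compounds this is 1 - 103/3561 = 0.971.
#'
#' @param labels Binary labels (0/1, logical, or factor).
#' @return Majority-class fraction in \[0.5, 1\].
#' @export
naive_baseline <- function(labels) {
  if (length(labels) == 0) stop_glio("empty labels", "input_error")
  tab <- table(labels)
  max(tab) / sum(tab)
}

#' Classification metrics at a fixed decision threshold
#'
#' @param labels True binary labels (0/1).
#' @param probs Predicted positive-class probabilities.
#' @param threshold Decision threshold for the confusion matrix. Default 0.5.
#' @return A list of class `metrics_record`: confusion counts `tp`, `fp`,
#'   `tn`, `fn`; `precision`, `recall`, `f1` (harmonic mean of precision and
#'   recall), `accuracy`; `roc_auc` and `pr_auc` from the probabilities
#'   (`NA` when the test labels are single-class).
#' @export
compute_metrics <- function(labels, probs, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  both <- length(unique(labels)) == 2
  roc_auc <- if (both) {
    as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  } else NA_real_
  pr_auc <- if (both) pr_auc_step(labels, probs) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, recall = recall, f1 = f1,
                 accuracy = (tp + tn) / length(labels),
                 roc_auc = roc_auc, pr_auc = pr_auc,
                 threshold = threshold),
            class = "metrics_record")
}

# Area under the precision-recall curve by the step-function (average
# precision) estimator: sum over ranked positives of precision-at-rank
# weighted by the recall increment.
pr_auc_step <- function(labels, probs) {
  ord <- order(probs, decreasing = TRUE)
  y <- as.integer(labels)[ord]
  n_pos <- sum(y)
  if (n_pos == 0) return(NA_real_)
  cum_tp <- cumsum(y)
  precision_at <- cum_tp / seq_along(y)
  sum(precision_at[y == 1]) / n_pos
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | precision %.3f recall %.3f F1 %.3f | ROC-AUC %.3f PR-AUC %.3f\n",
    x$accuracy, x$precision, x$recall, x$f1, x$roc_auc, x$pr_auc))
  cat(sprintf("confusion: TP %d FP %d TN %d FN %d (threshold %.2f)\n",
              x$tp, x$fp, x$tn, x$fn, x$threshold))
  invisible(x)
}
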