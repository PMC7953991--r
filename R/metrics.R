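## Confusion-matrix metric suite for the tassel/non-tassel classifier.
##
## Note the accuracy convention: accuracy = TP / (TP + FP + FN), i.e. the
## Jaccard index of the positive class, with no TN term. The standard
## accuracy (TP + TN) / total is exposed separately as `accuracy_standard`
## to avoid silent confusion.

#' Confusion matrix from counts
#' @param tp,fp,fn,tn non-negative counts.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn = 0) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v))) stopf("confusion counts must be non-negative integers")
  structure(as.list(v), class = "confusion_matrix")
}

#' Confusion matrix from predicted and true binary labels
#' @param predicted,truth vectors of 0/1 labels (1 = positive class).
#' @return a `confusion_matrix`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  confusion_matrix(tp = sum(predicted == 1 & truth == 1),
                   fp = sum(predicted == 1 & truth == 0),
                   fn = sum(predicted == 0 & truth == 1),
                   tn = sum(predicted == 0 & truth == 0))
}

#' Precision, recall, accuracy and F1 from a confusion matrix
#'
#' precision = TP/(TP+FP); recall = TP/(TP+FN);
#' accuracy = TP/(TP+FP+FN) (Jaccard convention, no TN term);
#' F1 = harmonic mean of precision and recall. Degenerate 0/0 ratios return 0
#' and set the `degenerate` flag instead of raising, so pipelines keep
#' running on empty frames.
#'
#' @param cm a `confusion_matrix`.
#' @return object of class `metric_set` with fields `precision`, `recall`,
#'   `accuracy`, `f1`, `accuracy_standard`, `degenerate`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- safe_div(cm$tp, cm$tp + cm$fp)
  recall <- safe_div(cm$tp, cm$tp + cm$fn)
  accuracy <- safe_div(cm$tp, cm$tp + cm$fp + cm$fn)
  f1 <- if (precision + recall == 0) { degenerate <- degenerate || cm$tp + cm$fp + cm$fn > 0; 0 }
        else 2 * precision * recall / (precision + recall)
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  accuracy_standard <- safe_div(cm$tp + cm$tn, total)
  structure(list(precision = precision, recall = recall, accuracy = accuracy,
                 f1 = f1, accuracy_standard = accuracy_standard,
                 degenerate = degenerate),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  accuracy %.4f  F1 %.4f%s\n",
              x$precision, x$recall, x$accuracy, x$f1,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}
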