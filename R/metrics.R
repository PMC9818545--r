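# Evaluation metrics: confusion matrix and one-vs-rest
# accuracy / precision / recall / F1 per class.

#' Confusion matrix
#'
#' Entry (r, c) counts samples with true class r predicted as class c.
#'
#' @param y_true,y_pred Class labels: 1-based integer indices or class-name
#'   characters (mapped through the canonical order when `classes` covers
#'   them).
#' @param classes Class names defining the matrix order; default the
#'   canonical four, or `c("cancerous","noncancerous")` style vectors for
#'   binary reports.
#' @return K x K integer matrix with dimnames `true` x `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = histo_classes()) {
  to_idx <- function(v) {
    if (is.character(v)) v <- match(v, classes)
    v
  }
  ti <- to_idx(y_true); pi <- to_idx(y_pred)
  if (length(ti) != length(pi)) stop("y_true and y_pred lengths differ")
  k <- length(classes)
  if (anyNA(ti) || anyNA(pi) || any(ti < 1 | ti > k | pi < 1 | pi > k)) {
    stop("label error: labels outside the class set")
  }
  m <- matrix(0L, k, k, dimnames = list(true = classes, predicted = classes))
  for (i in seq_along(ti)) m[ti[i], pi[i]] <- m[ti[i], pi[i]] + 1L
  m
}

#' One-vs-rest metrics for one class of a confusion matrix
#'
#' For the given class: TP is its diagonal entry, FP the rest of its
#' predicted column, FN the rest of its true row, TN everything else. Then
#' accuracy = (TP + TN) / total, precision = TP / (TP + FP),
#' recall = TP / (TP + FN), F1 = 2PR / (P + R) (harmonic mean). Any 0/0 is
#' reported as 0 with a warning.
#'
#' @param confusion K x K count matrix (rows true, columns predicted).
#' @param class_index 1-based class position.
#' @return Named numeric vector `precision`, `recall`, `f1`, `accuracy`.
#' @export
precision_recall_f1_accuracy <- function(confusion, class_index) {
  k <- nrow(confusion)
  stopifnot(class_index >= 1, class_index <= k)
  tp <- confusion[class_index, class_index]
  fp <- sum(confusion[, class_index]) - tp
  fn <- sum(confusion[class_index, ]) - tp
  tn <- sum(confusion) - tp - fp - fn
  ratio0 <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0); reporting 0")
      return(0)
    }
    num / den
  }
  precision <- ratio0(tp, tp + fp, "precision")
  recall <- ratio0(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  accuracy <- ratio0(tp + tn, sum(confusion), "accuracy")
  c(precision = precision, recall = recall, f1 = f1, accuracy = accuracy)
}

#' Full metrics report
#'
#' Confusion matrix, per-class one-vs-rest metrics and overall accuracy
#' (trace / total).
#'
#' @param y_true,y_pred Labels as in [confusion_matrix()].
#' @param classes Class name vector.
#' @return A `metrics_report`: list with `confusion`, `per_class`
#'   (data.frame), `overall_accuracy`, `n`.
#' @export
metrics_report <- function(y_true, y_pred, classes = histo_classes()) {
  cm <- confusion_matrix(y_true, y_pred, classes)
  per <- t(vapply(seq_along(classes),
                  function(i) precision_recall_f1_accuracy(cm, i),
                  numeric(4)))
  per <- data.frame(class = classes, per, row.names = NULL)
  structure(list(confusion = cm, per_class = per,
                 overall_accuracy = sum(diag(cm)) / max(sum(cm), 1),
                 n = sum(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics report (n = %d), overall accuracy %.4f\n",
              x$n, x$overall_accuracy))
  cat("Confusion (rows true, cols predicted):\n")
  print(x$confusion)
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(
    list(confusion = report$confusion,
         per_class = report$per_class,
         overall_accuracy = report$overall_accuracy,
         n = report$n),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
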