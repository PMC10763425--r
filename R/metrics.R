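#' Confusion matrix for binary classification
#'
#' Positive class is 1 (pneumonia).
#'
#' @param y_true,y_pred equal-length binary vectors.
#' @return a `confusion_matrix`: list with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    pn_stop("y_true and y_pred must have equal length",
            "pneumonet_contract_error")
  if (length(y_true) < 1L)
    pn_stop("need at least one prediction", "pneumonet_contract_error")
  cm_counts(sum(y_true == 1 & y_pred == 1), sum(y_true == 0 & y_pred == 1),
            sum(y_true == 0 & y_pred == 0), sum(y_true == 1 & y_pred == 0))
}

#' @rdname confusion_matrix
#' @param tp,fp,tn,fn non-negative cell counts, for building a confusion
#'   matrix directly from published counts.
#' @export
cm_counts <- function(tp, fp, tn, fn) {
  cm <- list(tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
             fn = as.integer(fn))
  if (any(unlist(cm) < 0L))
    pn_stop("confusion-matrix cells must be non-negative",
            "pneumonet_contract_error")
  class(cm) <- "confusion_matrix"
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("pneumonia", "normal"),
                              predicted = c("pneumonia", "normal")))
  print(m)
  invisible(x)
}

# a ratio that returns NA (with a warning) instead of failing on an empty
# denominator, so batch reports never abort
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined: zero denominator", what), call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Evaluation metrics from a confusion matrix
#'
#' `accuracy = (TP+TN)/total`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)` (sensitivity / true-positive rate),
#' `specificity = TN/(TN+FP)` (true-negative rate),
#' `f1 = 2 * precision * recall / (precision + recall)`.
#' Ratios with a zero denominator are reported as `NA` with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return the metric value in `[0,1]`, or `NA` if undefined.
#' @export
accuracy <- function(cm)
  safe_ratio(cm$tp + cm$tn, cm$tp + cm$fp + cm$tn + cm$fn, "accuracy")

#' @rdname accuracy
#' @export
precision <- function(cm) safe_ratio(cm$tp, cm$tp + cm$fp, "precision")

#' @rdname accuracy
#' @export
recall <- function(cm) safe_ratio(cm$tp, cm$tp + cm$fn, "recall")

#' @rdname accuracy
#' @export
sensitivity <- function(cm) recall(cm)

#' @rdname accuracy
#' @export
specificity <- function(cm) safe_ratio(cm$tn, cm$tn + cm$fp, "specificity")

#' @rdname accuracy
#' @export
f1_score <- function(cm) {
  p <- suppressWarnings(precision(cm))
  r <- suppressWarnings(recall(cm))
  if (is.na(p) || is.na(r) || p + r == 0) {
    warning("f1 undefined: zero denominator", call. = FALSE)
    return(NA_real_)
  }
  2 * p * r / (p + r)
}

#' Full metrics report
#'
#' @param cm a [confusion_matrix()].
#' @return a `metrics_report`: list with `accuracy`, `precision`, `recall`,
#'   `specificity`, `f1` and the `cm` itself.
#' @export
metrics_report <- function(cm) {
  structure(list(accuracy = accuracy(cm), precision = precision(cm),
                 recall = recall(cm), specificity = specificity(cm),
                 f1 = f1_score(cm), cm = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (m in c("accuracy", "precision", "recall", "specificity", "f1"))
    cat(sprintf("%-12s %s\n", m,
                ifelse(is.na(x[[m]]), "NA", sprintf("%.6f", x[[m]]))))
  cat(sprintf("counts       TP=%d FP=%d TN=%d FN=%d\n",
              x$cm$tp, x$cm$fp, x$cm$tn, x$cm$fn))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report a `metrics_report`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to a file).
#' @export
metrics_json <- function(report, path = NULL) {
  obj <- list(accuracy = report$accuracy, precision = report$precision,
              recall = report$recall, specificity = report$specificity,
              f1 = report$f1, tp = report$cm$tp, fp = report$cm$fp,
              tn = report$cm$tn, fn = report$cm$fn)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
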