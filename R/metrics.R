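#' Confusion-matrix counts for binary binding predictions
#'
#' Tallies the four outcome categories of a binding/non-binding
#' classification: TP (binding predicted binding), TN (non-binding
#' predicted non-binding), FP (non-binding predicted binding), FN
#' (binding predicted non-binding). Class 1 is always the binding
#' (minority) class.
#'
#' @param truth 0/1 vector of true labels.
#' @param predicted 0/1 vector of predicted labels, same length.
#' @return Object of class `confusion_counts`: list with integer fields
#'   `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion_counts(c(1, 0, 1, 0), c(1, 0, 0, 0))
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- check_binary_vector(truth, "truth")
  predicted <- check_binary_vector(predicted, "predicted")
  if (length(truth) != length(predicted))
    stop_("`truth` (length %d) and `predicted` (length %d) differ in length",
          length(truth), length(predicted))
  structure(list(
    tp = sum(truth == 1L & predicted == 1L),
    tn = sum(truth == 0L & predicted == 0L),
    fp = sum(truth == 0L & predicted == 1L),
    fn = sum(truth == 1L & predicted == 0L)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Classification accuracy
#'
#' Correct predictions (TP + TN) over all evaluated conformations.
#'
#' @param c A [confusion_counts()] object.
#' @return Proportion in \[0, 1\].
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0L) stop_("accuracy is undefined on zero evaluated rows")
  (c$tp + c$tn) / total
}

#' Sensitivity (binding-conformation detection rate)
#'
#' Correctly predicted binding conformations over all truly binding
#' conformations: TP / (TP + FN). This is the quantity the imbalance-aware
#' cascade is designed to raise.
#'
#' @param c A [confusion_counts()] object.
#' @return Proportion in \[0, 1\].
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0L)
    stop_("sensitivity is undefined: no binding conformations in the evaluated set")
  c$tp / (c$tp + c$fn)
}
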