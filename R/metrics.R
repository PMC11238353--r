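# Confusion-matrix bookkeeping and scoring functions.
#
# The positive class throughout is the adverse outcome (pulp exposure = 1).
# Degenerate denominators follow the usual convention: a precision or recall
# whose denominator is 0 is defined as 0, and a class F1 is 0 when
# precision + recall = 0, so every simulated trial remains scoreable.

#' Confusion counts for binary predictions
#'
#' Tallies true/false positives and negatives of a binary prediction vector
#' against ground truth. The positive class (1) is the adverse outcome, e.g.
#' pulp exposure during excavation.
#'
#' @param predictions Binary (0/1) vector of predicted labels.
#' @param truth Binary (0/1) vector of true labels, same length.
#' @return An object of class `confusion_counts`: a list with integer fields
#'   `tp`, `fp`, `fn`, `tn`. Their sum equals the number of scored cases.
#' @examples
#' confusion(c(1, 0, 1, 0), c(1, 1, 0, 0))
#' @export
confusion <- function(predictions, truth) {
  predictions <- .check_binary(predictions, "predictions")
  truth <- .check_binary(truth, "truth")
  if (length(predictions) != length(truth))
    stop("`predictions` and `truth` must have the same length", call. = FALSE)
  structure(list(
    tp = sum(predictions == 1L & truth == 1L),
    fp = sum(predictions == 1L & truth == 0L),
    fn = sum(predictions == 0L & truth == 1L),
    tn = sum(predictions == 0L & truth == 0L)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Precision and recall from confusion counts
#'
#' Precision = TP / (TP + FP); recall = TP / (TP + FN). A zero denominator
#' yields 0.
#'
#' @param counts A `confusion_counts` object (or list with tp/fp/fn/tn).
#' @return Named numeric vector with elements `precision` and `recall`.
#' @export
precision_recall <- function(counts) {
  c(precision = .sdiv(counts$tp, counts$tp + counts$fp),
    recall    = .sdiv(counts$tp, counts$tp + counts$fn))
}

# Macro-averaged F1 from (possibly non-integer, e.g. expected) counts.
# Class 1 is scored from (tp, fp, fn); class 0 by relabelling 0 as positive,
# i.e. from (tn, fn, fp). Vectorised over counts.
.macro_f1_counts <- function(tp, fp, fn, tn) {
  p1 <- .sdiv(tp, tp + fp)
  r1 <- .sdiv(tp, tp + fn)
  f1_pos <- ifelse(p1 + r1 > 0, 2 * p1 * r1 / (p1 + r1), 0)
  p0 <- .sdiv(tn, tn + fn)
  r0 <- .sdiv(tn, tn + fp)
  f1_neg <- ifelse(p0 + r0 > 0, 2 * p0 * r0 / (p0 + r0), 0)
  (f1_pos + f1_neg) / 2
}

# Macro-F1 column-wise over a logical prediction matrix (cases x trials);
# the fast path used by the Monte-Carlo engine.
.macro_f1_cols <- function(pred_mat, truth_logical) {
  tp <- colSums(pred_mat & truth_logical)
  fp <- colSums(pred_mat & !truth_logical)
  fn <- colSums(!pred_mat & truth_logical)
  tn <- colSums(!pred_mat & !truth_logical)
  .macro_f1_counts(tp, fp, fn, tn)
}

#' Macro-averaged F1 score
#'
#' Per-class F1 (harmonic mean of precision and recall) is computed for the
#' positive class (1) and for the negative class (0, scored by relabelling 0
#' as positive), then averaged with equal weight — both classes are treated
#' as equally important regardless of prevalence.
#'
#' @inheritParams confusion
#' @return Macro-F1 in `[0, 1]`; equals 1 iff `predictions == truth`.
#' @examples
#' macro_f1(c(1, 0, 1, 0), c(1, 1, 0, 0)) # both class F1 = 0.5 -> 0.5
#' @export
macro_f1 <- function(predictions, truth) {
  cc <- confusion(predictions, truth)
  .macro_f1_counts(cc$tp, cc$fp, cc$fn, cc$tn)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity; the knob used to parameterise the
#' AI-accuracy sensitivity sweep. A class absent from `truth` contributes 0
#' (same degenerate-denominator convention as [precision_recall()]).
#'
#' @inheritParams confusion
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(predictions, truth) {
  cc <- confusion(predictions, truth)
  sens <- .sdiv(cc$tp, cc$tp + cc$fn)
  spec <- .sdiv(cc$tn, cc$tn + cc$fp)
  (sens + spec) / 2
}
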