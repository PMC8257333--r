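# Pixelwise evaluation: confusion-matrix rates and volume-overlap metrics.
#
# In-region pixels are the positive class. Rates are reported on [0, 1];
# Dice and VOE as percentages on [0, 100]; RVD as a signed percentage.
# Two false-positive-rate variants are exposed: `fpr` follows the
# FP / (FP + FN) form used by the source evaluation protocol, and
# `fpr_conventional` is the textbook FP / (FP + TN).

#' Pixelwise confusion counts
#'
#' @param pred,truth Logical masks of identical shape (`TRUE` = in-region).
#' @return Object of class `confusion_counts`: list with integer `tp`,
#'   `tn`, `fp`, `fn` summing to the number of pixels.
#' @export
confusion_counts <- function(pred, truth) {
  check_mask(pred, "pred")
  check_mask(truth, "truth")
  check_same_shape(pred, truth, "pred", "truth")
  structure(list(tp = sum(pred & truth), tn = sum(!pred & !truth),
                 fp = sum(pred & !truth), fn = sum(!pred & truth)),
            class = "confusion_counts")
}

safe_rate <- function(num, den) if (den == 0) NaN else num / den

#' Confusion-matrix rates
#'
#' Sensitivity (TPR) = TP/(FN+TP); specificity (TNR) = TN/(FP+TN);
#' precision (PPV) = TP/(FP+TP); `fpr` = FP/(FP+FN) (protocol form);
#' `fpr_conventional` = FP/(FP+TN); accuracy = (TP+TN)/all. A
#' zero-denominator rate is `NaN` (undefined), never an error.
#'
#' @param counts A `confusion_counts` object.
#' @return Named list of the six rates.
#' @export
rates <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, list(
    sensitivity = safe_rate(tp, fn + tp),
    specificity = safe_rate(tn, fp + tn),
    precision = safe_rate(tp, fp + tp),
    fpr = safe_rate(fp, fp + fn),
    fpr_conventional = safe_rate(fp, fp + tn),
    accuracy = safe_rate(tp + tn, tp + tn + fp + fn)
  ))
}

#' Dice similarity (percentage)
#'
#' `100 * 2 |A n B| / (|A| + |B|)`; two empty masks agree perfectly, so
#' the value is 100 by convention.
#'
#' @param set1,set2 Logical masks of identical shape.
#' @return Percentage in \[0, 100\].
#' @export
dice <- function(set1, set2) {
  check_mask(set1, "set1")
  check_mask(set2, "set2")
  check_same_shape(set1, set2, "set1", "set2")
  denom <- sum(set1) + sum(set2)
  if (denom == 0) return(100)
  100 * 2 * sum(set1 & set2) / denom
}

#' Volume overlap error (percentage)
#'
#' `100 * (1 - Jaccard)`; 0 for two empty masks (perfect-agreement limit).
#'
#' @inheritParams dice
#' @return Percentage in \[0, 100\].
#' @export
voe <- function(set1, set2) {
  check_mask(set1, "set1")
  check_mask(set2, "set2")
  check_same_shape(set1, set2, "set1", "set2")
  union_size <- sum(set1 | set2)
  if (union_size == 0) return(0)
  100 * (1 - sum(set1 & set2) / union_size)
}

#' Relative volume difference (signed percentage)
#'
#' `100 * (|set1| - |set2|) / |set2|` with `set2` the ground truth;
#' negative values indicate undersegmentation.
#'
#' @inheritParams dice
#' @return Signed percentage.
#' @export
rvd <- function(set1, set2) {
  check_mask(set1, "set1")
  check_mask(set2, "set2")
  check_same_shape(set1, set2, "set1", "set2")
  v2 <- sum(set2)
  if (v2 == 0) stop_validation("rvd: ground-truth mask is empty")
  100 * (sum(set1) - v2) / v2
}

#' Eight-metric evaluation report
#'
#' Assembles sensitivity, specificity, precision, both FPR variants,
#' accuracy, Dice, VOE, and RVD from a single confusion-count pass.
#'
#' @param pred Predicted mask (logical matrix).
#' @param truth Ground-truth mask, identical shape.
#' @return A one-row `data.frame` of class `eval_report` with columns
#'   `tp, tn, fp, fn, sensitivity, specificity, precision, fpr_paper,
#'   fpr_conventional, accuracy, dice, voe, rvd`.
#' @export
evaluate <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  r <- rates(cc)
  out <- data.frame(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
                    sensitivity = r$sensitivity,
                    specificity = r$specificity,
                    precision = r$precision,
                    fpr_paper = r$fpr,
                    fpr_conventional = r$fpr_conventional,
                    accuracy = r$accuracy,
                    dice = dice(pred, truth),
                    voe = voe(pred, truth),
                    rvd = if (sum(truth) > 0) rvd(pred, truth) else NaN)
  class(out) <- c("eval_report", class(out))
  out
}
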