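#' Pixelwise confusion counts between predicted and true masks
#'
#' Foreground is the positive class. An optional [roi_box] restricts
#' counting to that sub-window.
#'
#' @param pred,truth logical matrices of the same shape.
#' @param roi optional [roi_box].
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn` (their sum equals the ROI pixel count).
#' @export
confusion_counts <- function(pred, truth, roi = NULL) {
  if (!all(dim(pred) == dim(truth))) stop("mask shape mismatch")
  if (!is.null(roi)) {
    ri <- (roi$row_start + 1L):roi$row_end
    ci <- (roi$col_start + 1L):roi$col_end
    pred <- pred[ri, ci, drop = FALSE]
    truth <- truth[ri, ci, drop = FALSE]
  }
  structure(list(tp = sum(pred & truth),
                 fp = sum(pred & !truth),
                 tn = sum(!pred & !truth),
                 fn = sum(!pred & truth)),
            class = "confusion_counts")
}

#' Segmentation scores from confusion counts
#'
#' accuracy = (tp + tn) / total; sensitivity = tp / (tp + fn);
#' specificity = tn / (tn + fp); dice = 2 tp / (2 tp + fp + fn).
#' A 0/0 case yields `NA` (an explicit undefined marker), never a silent 0.
#' All values are fractions in \[0, 1\]; multiply by 100 only at the
#' reporting layer.
#'
#' @param counts a [confusion_counts] object.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `dice`.
#' @export
segmentation_scores <- function(counts) {
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) stop("confusion counts are empty")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = (counts$tp + counts$tn) / total,
       sensitivity = safe(counts$tp, counts$tp + counts$fn),
       specificity = safe(counts$tn, counts$tn + counts$fp),
       dice = safe(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn))
}

#' Dice overlap between two masks
#' @param a,b logical matrices of the same shape.
#' @export
dice_score <- function(a, b) segmentation_scores(confusion_counts(a, b))$dice
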