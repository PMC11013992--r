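# Segmentation metrics on an explicit confusion matrix.

#' Confusion matrix of a point-wise prediction
#'
#' Entry `[i, j]` counts points whose true class is `i-1` and predicted
#' class is `j-1` (classes are 0-based values, rows/columns 1-based).
#'
#' @param truth,pred integer label vectors of equal length, values in
#'   `0..C-1`.
#' @param C number of classes.
#' @return C x C `confusion_matrix` of counts.
#' @export
confusion <- function(truth, pred, C) {
  C <- check_count(C, "C")
  if (length(truth) != length(pred)) stop_dfseg("truth/pred length mismatch")
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (any(truth < 0L | truth >= C) || any(pred < 0L | pred >= C)) {
    stop_dfseg("labels outside 0..%d", C - 1L)
  }
  cm <- matrix(tabulate(truth * C + pred + 1L, nbins = C * C),
               nrow = C, ncol = C, byrow = TRUE)
  dimnames(cm) <- list(truth = 0:(C - 1L), pred = 0:(C - 1L))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Overall point accuracy
#'
#' Fraction of points whose predicted label matches the true label:
#' `trace(cm) / sum(cm)`.
#'
#' @param cm a [confusion()] matrix.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop_dfseg("empty confusion matrix")
  sum(diag(cm)) / total
}

#' @noRd
per_class_iou <- function(cm) {
  tp <- diag(cm)
  denom <- rowSums(cm) + colSums(cm) - tp
  iou <- ifelse(denom > 0, tp / denom, NA_real_)
  names(iou) <- rownames(cm)
  iou
}

#' Mean intersection over union
#'
#' Per class i, `IoU_i = S_ii / (sum_j S_ij + sum_j S_ji - S_ii)`, averaged
#' over classes. Classes absent from both truth and prediction have an
#' undefined IoU; by default (`include_empty = FALSE`) they are excluded
#' from the mean. With `include_empty = TRUE` the mean still skips the
#' undefined entries but is taken in the fixed class order, which matters
#' only for reporting per-class values.
#'
#' @param cm a [confusion()] matrix.
#' @param include_empty see above.
#' @return mIoU in `[0, 1]`.
#' @export
miou <- function(cm, include_empty = FALSE) {
  if (sum(cm) <= 0) stop_dfseg("empty confusion matrix")
  iou <- per_class_iou(cm)
  if (all(is.na(iou))) stop_dfseg("no class present in truth or prediction")
  mean(iou, na.rm = TRUE)
}
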