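# Segmentation evaluation: confusion counts and the five standard overlap
# statistics (VOE, precision, accuracy, DSC, RVD).

#' Confusion counts between a segmentation and the ground truth
#'
#' With A the segmented mask and B the truth: TP = |A intersect B|,
#' FP = |A \ B|, FN = |B \ A|, TN = the rest.
#'
#' @param segmented logical/binary array (any dimensionality).
#' @param truth logical/binary array, same shape.
#' @return named integer vector `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(segmented, truth) {
  if (!identical(dim(segmented), dim(truth)) &&
      !(is.null(dim(segmented)) && is.null(dim(truth)) &&
        length(segmented) == length(truth)))
    stop("segmented and truth must have identical shape")
  a <- segmented != 0
  b <- truth != 0
  tp <- sum(a & b)
  c(TP = tp, FP = sum(a) - tp, FN = sum(b) - tp,
    TN = sum(!a & !b))
}

#' Overlap report for one mask pair
#'
#' Computes, from the confusion counts:
#' \itemize{
#'   \item VOE (volumetric overlap error, percent):
#'     `100 * (1 - |A intersect B| / |A union B|)`; 0 is perfect.
#'   \item precision `TP / (TP + FP)`;
#'   \item accuracy `(TP + TN) / total`;
#'   \item DSC (Dice) `2 TP / (2 TP + FP + FN)`;
#'   \item RVD (relative volume difference, signed percent)
#'     `100 * (|A| - |B|) / |B|`; negative = under-segmentation. An
#'     absolute companion `RVD_abs` is also reported.
#' }
#' Convention for two empty masks: VOE 0, DSC 1 (perfect agreement on
#' nothing). RVD is `NA` when the truth is empty.
#'
#' @inheritParams confusion_counts
#' @param spacing optional voxel spacing (mm) to also report volumes in ml.
#' @return object of class `overlap_report` (a one-row data.frame with
#'   TP/FP/FN/TN, VOE, precision, accuracy, DSC, RVD, RVD_abs and optional
#'   `volume_segmented_ml` / `volume_truth_ml`).
#' @export
compute_report <- function(segmented, truth, spacing = NULL) {
  cc <- confusion_counts(segmented, truth)
  tp <- cc["TP"]; fp <- cc["FP"]; fn <- cc["FN"]; tn <- cc["TN"]
  union <- tp + fp + fn
  na <- tp + fp   # |A|
  nb <- tp + fn   # |B|
  voe <- if (union == 0) 0 else 100 * (1 - tp / union)
  dsc <- if (union == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  precision <- if (na == 0) NA_real_ else tp / na
  accuracy <- (tp + tn) / sum(cc)
  rvd <- if (nb == 0) NA_real_ else 100 * (na - nb) / nb
  rep <- data.frame(TP = unname(tp), FP = unname(fp), FN = unname(fn),
                    TN = unname(tn),
                    VOE = unname(voe), precision = unname(precision),
                    accuracy = unname(accuracy), DSC = unname(dsc),
                    RVD = unname(rvd), RVD_abs = unname(abs(rvd)))
  if (!is.null(spacing)) {
    vox_ml <- prod(spacing) / 1000
    rep$volume_segmented_ml <- unname(na * vox_ml)
    rep$volume_truth_ml <- unname(nb * vox_ml)
  }
  class(rep) <- c("overlap_report", class(rep))
  rep
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "VOE %.2f%%  DSC %.4f  precision %.4f  accuracy %.4f  RVD %+.2f%%\n",
    x$VOE, x$DSC, x$precision, x$accuracy, x$RVD))
  cat(sprintf("TP %d  FP %d  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Evaluate a segmentation file against a ground-truth file
#'
#' Reads two NIfTI label volumes (nonzero = foreground) and reports the
#' overlap statistics.
#'
#' @param segmented_path,truth_path NIfTI files.
#' @return an [compute_report()] result.
#' @export
evaluate_masks <- function(segmented_path, truth_path) {
  a <- read_mask(segmented_path)
  b <- read_mask(truth_path)
  compute_report(a, b)
}
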