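# Evaluation indices: voxelwise confusion counts, accuracy, and the Dice
# similarity coefficient, per volume and pooled.

#' Confusion counts between two binary masks
#'
#' @param pred,truth Binary arrays of identical shape.
#' @return A `confusion_counts` list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim2(pred), dim2(truth))) stop("pred and truth shapes differ")
  check_binary(pred, "pred")
  check_binary(truth, "truth")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn), class = "confusion_counts")
}

#' Segmentation accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`: the proportion of voxels labelled
#' correctly.
#'
#' @param c A [confusion_counts()].
#' @return Scalar in `[0, 1]`.
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop("no voxels evaluated")
  (c$TP + c$TN) / total
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)`, i.e. `2|A n B| / (|A| + |B|)`. When both masks
#' are empty (denominator 0) the overlap is perfect by convention and 1 is
#' returned with a message.
#'
#' @param c A [confusion_counts()].
#' @return Scalar in `[0, 1]`; 1 is complete overlap, 0 complete deviation.
#' @export
dice_coefficient <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  denom <- 2 * c$TP + c$FP + c$FN
  if (denom == 0) {
    message("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * c$TP / denom
}

#' Evaluate predicted mask volumes against ground truth
#'
#' Pairs `segmentation-*.nii` files in the two directories by case index and
#' reports per-volume accuracy and Dice plus a pooled row in which confusion
#' counts are summed across volumes before division (pooled Dice is not the
#' mean of per-volume Dice).
#'
#' @param pred_dir Directory of predicted masks (LiTS `segmentation-*` naming).
#' @param truth_dir Directory of ground-truth masks.
#' @return Data frame, one row per volume plus a final `pooled` row, with
#'   columns `case`, `TP`, `FP`, `FN`, `TN`, `accuracy`, `dice`.
#' @export
evaluate_volumes <- function(pred_dir, truth_dir) {
  list_masks <- function(d) {
    fs <- list.files(d, pattern = "^segmentation-[0-9]+\\.nii(\\.gz)?$",
                     full.names = TRUE)
    idx <- as.integer(sub("^segmentation-([0-9]+)\\..*$", "\\1", basename(fs)))
    stats::setNames(fs, idx)
  }
  preds <- list_masks(pred_dir)
  truths <- list_masks(truth_dir)
  only_pred <- setdiff(names(preds), names(truths))
  only_truth <- setdiff(names(truths), names(preds))
  if (length(only_pred) || length(only_truth)) {
    stop("unpaired files: ",
         paste(c(sprintf("pred-only case %s", only_pred),
                 sprintf("truth-only case %s", only_truth)), collapse = "; "))
  }
  cases <- sort(as.integer(names(preds)))
  rows <- lapply(cases, function(i) {
    cc <- confusion_counts(read_mask(preds[[as.character(i)]]),
                           read_mask(truths[[as.character(i)]]))
    data.frame(case = as.character(i), TP = cc$TP, FP = cc$FP, FN = cc$FN,
               TN = cc$TN, accuracy = accuracy(cc),
               dice = dice_coefficient(cc), stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  pooled <- structure(list(TP = sum(rep$TP), FP = sum(rep$FP),
                           FN = sum(rep$FN), TN = sum(rep$TN)),
                      class = "confusion_counts")
  rbind(rep, data.frame(case = "pooled", TP = pooled$TP, FP = pooled$FP,
                        FN = pooled$FN, TN = pooled$TN,
                        accuracy = accuracy(pooled),
                        dice = dice_coefficient(pooled),
                        stringsAsFactors = FALSE))
}
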