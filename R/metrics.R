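# Pixel confusion-matrix construction and the segmentation scores derived
# from it (accuracy, Jaccard index, Dice coefficient), with per-image
# aggregation as used for test-set reporting.

#' Pixel confusion counts between two binary masks
#'
#' Tallies true/false positives and negatives pixelwise, with 1 = lesion.
#'
#' @param predicted,truth binary masks (`0/1` numeric or logical) of
#'   identical shape.
#' @return object of class `confusion_counts` with fields `TP`, `TN`, `FP`,
#'   `FN` and the pixel total `n`.
#' @export
#' @examples
#' confusion_from_masks(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 0, 0, 1), 2))
confusion_from_masks <- function(predicted, truth) {
  if (is.logical(predicted)) predicted <- predicted * 1L
  if (is.logical(truth)) truth <- truth * 1L
  dp <- dim(predicted) %||% length(predicted)
  dt <- dim(truth) %||% length(truth)
  if (!identical(as.integer(dp), as.integer(dt)))
    stop("predicted and truth masks must have the same shape")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("masks must be binary (values in {0, 1})")
  p <- predicted == 1
  t <- truth == 1
  counts <- list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t))
  counts$n <- counts$TP + counts$TN + counts$FP + counts$FN
  structure(counts, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("pixel confusion: TP %d  TN %d  FP %d  FN %d  (n = %d)\n",
              x$TP, x$TN, x$FP, x$FN, x$n))
  invisible(x)
}

#' Segmentation scores from confusion counts
#'
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, `JAC = TP / (TP + FP + FN)`,
#' `DICE = 2*TP / (2*TP + FP + FN)`. When the union is empty
#' (`TP = FP = FN = 0`, both masks all-background) JAC and DICE are defined
#' as 1: agreement on the absence of a lesion is scored as perfect.
#'
#' @param counts a `confusion_counts` object (or a list with fields
#'   `TP`, `TN`, `FP`, `FN`).
#' @return object of class `seg_scores`: named numeric `c(ACC, JAC, DICE)`.
#' @export
#' @examples
#' seg_score(list(TP = 50, TN = 25, FP = 10, FN = 15))
seg_score <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be nonnegative")
  total <- tp + tn + fp + fn
  if (total == 0) stop("confusion counts are all zero")
  acc <- (tp + tn) / total
  if (tp + fp + fn == 0) {
    jac <- 1
    dice <- 1
  } else {
    jac <- tp / (tp + fp + fn)
    dice <- 2 * tp / (2 * tp + fp + fn)
  }
  structure(c(ACC = acc, JAC = jac, DICE = dice), class = "seg_scores")
}

#' @export
print.seg_scores <- function(x, ...) {
  cat(sprintf("ACC %.4f  JAC %.4f  DICE %.4f\n",
              x[["ACC"]], x[["JAC"]], x[["DICE"]]))
  invisible(x)
}

#' @rdname seg_score
#' @param predicted,truth binary masks, passed to [confusion_from_masks()].
#' @export
score_masks <- function(predicted, truth) {
  seg_score(confusion_from_masks(predicted, truth))
}

#' Aggregate per-image scores to a dataset summary
#'
#' Arithmetic mean of each metric over images (the per-image averaging
#' convention of the ISIC challenges), alongside the per-image vectors for
#' box-plot style inspection.
#'
#' @param scores a non-empty list of `seg_scores`, or a data frame with
#'   columns `ACC`, `JAC`, `DICE` (extra columns such as `id` are kept).
#' @return list with `per_image` (data frame), `mean` (named numeric) and
#'   `n`.
#' @export
aggregate_scores <- function(scores) {
  if (is.data.frame(scores)) {
    df <- scores
  } else {
    if (!is.list(scores) || length(scores) == 0L)
      stop("scores must be a non-empty list or data frame")
    df <- as.data.frame(do.call(rbind, lapply(scores, unclass)))
  }
  if (nrow(df) == 0L) stop("scores must be non-empty")
  if (!all(c("ACC", "JAC", "DICE") %in% names(df)))
    stop("scores must contain ACC, JAC and DICE")
  list(per_image = df,
       mean = c(ACC = mean(df$ACC), JAC = mean(df$JAC), DICE = mean(df$DICE)),
       n = nrow(df))
}

#' Export an evaluation report
#'
#' Writes per-image scores as CSV (one row per image: id, ACC, JAC, DICE)
#' and the dataset summary as JSON.
#'
#' @param report an `eval_report` from [evaluate()] or the result of
#'   [aggregate_scores()].
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return the report, invisibly.
#' @export
write_scores <- function(report, csv = NULL, json = NULL) {
  per_image <- report$per_image
  if (!is.null(csv)) {
    utils::write.csv(per_image, csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(mean = as.list(report$mean), n = report$n),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
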