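# Confusion-matrix segmentation metrics. Lesion pixels are the positive
# class throughout.

#' Pixel confusion matrix of two binary masks
#'
#' @param pred,gt 0/1 matrices of equal shape; `gt` is the reference.
#' @return Object of class `confusion_matrix`: list with integer counts
#'   `TP`, `FP`, `FN`, `TN`.
#' @examples
#' confusion(matrix(c(1, 0, 1, 1), 2), matrix(c(1, 1, 0, 1), 2))
#' @export
confusion <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("pred and gt shapes differ", call. = FALSE)
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1))) {
    stop("masks must be binary (0/1)", call. = FALSE)
  }
  p <- pred == 1
  g <- gt == 1
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 FN = sum(!p & g), TN = sum(!p & !g)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FP %d  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

# degenerate-denominator convention: a prediction/reference pair with no
# positive pixels anywhere relevant to the metric counts as a correct
# rejection (metric 1); any other zero denominator reports 0 and is flagged
# via the "degenerate" attribute.
.safe_ratio <- function(num, den, all_empty) {
  if (den > 0) return(num / den)
  structure(if (all_empty) 1 else 0, degenerate = !all_empty)
}

#' Segmentation metrics from a confusion matrix
#'
#' `accuracy` is (TP+TN)/(TP+FP+TN+FN); `dice` is 2TP/(2TP+FP+FN); `iou` is
#' TP/(TP+FP+FN); `sensitivity` is TP/(TP+FN); `specificity` is TN/(TN+FP).
#' When prediction and reference are both empty, Dice, IoU and sensitivity
#' are defined as 1 (correct rejection); any other zero denominator yields 0
#' with attribute `degenerate = TRUE`.
#'
#' @param cm A [confusion()] result.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  (cm$TP + cm$TN) / (cm$TP + cm$FP + cm$TN + cm$FN)
}

#' @rdname accuracy
#' @export
dice <- function(cm) .safe_ratio(2 * cm$TP, 2 * cm$TP + cm$FP + cm$FN,
                                 cm$TP + cm$FP + cm$FN == 0)

#' @rdname accuracy
#' @export
iou <- function(cm) .safe_ratio(cm$TP, cm$TP + cm$FP + cm$FN,
                                cm$TP + cm$FP + cm$FN == 0)

#' @rdname accuracy
#' @export
sensitivity <- function(cm) .safe_ratio(cm$TP, cm$TP + cm$FN,
                                        cm$TP + cm$FP + cm$FN == 0)

#' @rdname accuracy
#' @export
specificity <- function(cm) .safe_ratio(cm$TN, cm$TN + cm$FP,
                                        cm$TN + cm$FP + cm$TP + cm$FN == 0)

.metric_row <- function(cm) {
  tibble::tibble(accuracy = as.numeric(accuracy(cm)),
                 iou = as.numeric(iou(cm)),
                 dice = as.numeric(dice(cm)),
                 sensitivity = as.numeric(sensitivity(cm)),
                 specificity = as.numeric(specificity(cm)))
}

#' Evaluate predicted masks against references
#'
#' Two aggregations are reported: `"pooled"` sums confusion counts over all
#' slices before applying the metric formulas (the headline number), and
#' `"per_slice_mean"` averages per-slice metrics.
#'
#' @param pred_masks,gt_masks Lists of 0/1 matrices, aligned pairwise.
#' @param mode `"both"` (default), `"pooled"` or `"per_slice_mean"`.
#' @return Tibble with one row per requested mode and columns `mode`,
#'   `n_slices`, `accuracy`, `iou`, `dice`, `sensitivity`, `specificity`.
#' @export
evaluate_masks <- function(pred_masks, gt_masks,
                           mode = c("both", "pooled", "per_slice_mean")) {
  mode <- match.arg(mode)
  if (length(pred_masks) != length(gt_masks)) {
    stop("pred_masks and gt_masks have different lengths", call. = FALSE)
  }
  if (length(pred_masks) == 0L) stop("no masks to evaluate", call. = FALSE)
  cms <- Map(confusion, pred_masks, gt_masks)
  rows <- list()
  if (mode %in% c("both", "pooled")) {
    pooled <- structure(list(TP = sum(vapply(cms, `[[`, numeric(1), "TP")),
                             FP = sum(vapply(cms, `[[`, numeric(1), "FP")),
                             FN = sum(vapply(cms, `[[`, numeric(1), "FN")),
                             TN = sum(vapply(cms, `[[`, numeric(1), "TN"))),
                        class = "confusion_matrix")
    rows$pooled <- cbind(tibble::tibble(mode = "pooled", n_slices = length(cms)),
                         .metric_row(pooled))
  }
  if (mode %in% c("both", "per_slice_mean")) {
    per <- do.call(rbind, lapply(cms, .metric_row))
    rows$per <- cbind(tibble::tibble(mode = "per_slice_mean", n_slices = length(cms)),
                      tibble::as_tibble(as.list(colMeans(per))))
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' Write a metric report to CSV
#'
#' @param report Tibble from [evaluate_masks()] (optionally with extra
#'   identifying columns).
#' @param path Output CSV path.
#' @export
write_metric_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
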