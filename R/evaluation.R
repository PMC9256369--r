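## Pixel-level evaluation of a segmentation against ground truth:
## confusion counts, the sensitivity / accuracy / specificity triple, the
## under- / over-segmentation regime taxonomy, and per-image results tables.

#' Pixel-level confusion counts
#'
#' True/false positives and negatives over the evaluated pixels (those
#' inside the FOV when a mask is given, all pixels otherwise).
#'
#' @param pred predicted logical vessel mask.
#' @param truth ground-truth logical vessel mask.
#' @param fov optional logical field-of-view mask.
#' @return object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth, fov = NULL) {
  stopifnot(is.logical(pred), is.logical(truth),
            identical(dim(pred), dim(truth)))
  if (!is.null(fov)) {
    stopifnot(identical(dim(fov), dim(pred)))
    pred <- pred[fov]; truth <- truth[fov]
  }
  structure(list(tp = sum(pred & truth), tn = sum(!pred & !truth),
                 fp = sum(pred & !truth), fn = sum(!pred & truth)),
            class = "confusion_counts")
}

#' Sensitivity, accuracy and specificity
#'
#' `Sen = TP/(TP+FN)`, `Acc = (TP+TN)/(TP+TN+FP+FN)`, `Sp = TN/(FP+TN)`.
#' A zero denominator yields `NA` (the in-band undefined flag) rather than
#' an error; undefined values are excluded from table averages.
#'
#' @param counts a [confusion_counts] object.
#' @return object of class `metric_triple` with fields `sensitivity`,
#'   `accuracy`, `specificity` (each in `[0, 1]` or `NA`).
#' @export
metric_triple <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  structure(list(
    sensitivity = safe_div(counts$tp, counts$tp + counts$fn),
    accuracy = safe_div(counts$tp + counts$tn, total),
    specificity = safe_div(counts$tn, counts$fp + counts$tn)),
    class = "metric_triple")
}

#' Classify the segmentation regime
#'
#' High specificity with low sensitivity marks under-segmentation (vessels
#' missed); low specificity with high sensitivity marks over-segmentation
#' (background recognised as vessel); both high marks accurate
#' segmentation.
#'
#' @param m a [metric_triple] with defined sensitivity and specificity.
#' @param high_cut,low_cut the qualitative "higher side" / "lower side"
#'   cutoffs (defaults 0.9 and 0.5).
#' @return one of `"under_segmented"`, `"over_segmented"`, `"accurate"`,
#'   `"indeterminate"`.
#' @export
classify_regime <- function(m, high_cut = 0.9, low_cut = 0.5) {
  stopifnot(inherits(m, "metric_triple"))
  sen <- m$sensitivity; sp <- m$specificity
  if (is.na(sen) || is.na(sp)) {
    stop("regime classification needs defined sensitivity and specificity",
         call. = FALSE)
  }
  if (sen >= high_cut && sp >= high_cut) return("accurate")
  if (sp >= high_cut && sen <= low_cut) return("under_segmented")
  if (sen >= high_cut && sp <= low_cut) return("over_segmented")
  "indeterminate"
}

#' Evaluate a set of segmentations
#'
#' One row of Sen / Acc / Sp per image plus a final `"Average"` row of
#' unweighted arithmetic means over the defined values.
#'
#' @param pairs non-empty list; each element a list with components `pred`,
#'   `truth` and optionally `fov`.
#' @param labels image labels (default `image_01`, ...).
#' @return `data.frame` with columns `image`, `sensitivity`, `accuracy`,
#'   `specificity`.
#' @export
evaluate_set <- function(pairs, labels = NULL) {
  if (length(pairs) == 0L) stop("empty evaluation set", call. = FALSE)
  if (is.null(labels)) {
    labels <- sprintf("image_%02d", seq_along(pairs))
  }
  stopifnot(length(labels) == length(pairs))
  rows <- lapply(pairs, function(p) {
    m <- metric_triple(confusion_counts(p$pred, p$truth, p$fov))
    c(m$sensitivity, m$accuracy, m$specificity)
  })
  tab <- do.call(rbind, rows)
  avg <- colMeans(tab, na.rm = TRUE)
  data.frame(image = c(labels, "Average"),
             sensitivity = c(tab[, 1], avg[1]),
             accuracy = c(tab[, 2], avg[2]),
             specificity = c(tab[, 3], avg[3]),
             stringsAsFactors = FALSE)
}
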