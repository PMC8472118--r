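# Pixel-level evaluation: confusion counts, the six derived metrics (as
# percentages), and per-patient cohort summaries.

METRIC_NAMES <- c("dsc", "accuracy", "sensitivity", "specificity", "ppv", "npv")

#' Confusion counts between a predicted and a ground-truth mask
#'
#' Voxel-wise TP/TN/FP/FN over whole arrays of any (matching) shape. TP counts
#' voxels correctly predicted as meniscus, TN voxels correctly predicted as
#' background, FP background voxels predicted as meniscus and FN meniscus
#' voxels predicted as background.
#'
#' @param pred,gt Binary arrays of identical shape.
#' @return An object of class `confusion_counts`: named integer vector with
#'   elements `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim2(pred), dim2(gt))) stop("pred and gt shapes differ")
  p <- as.integer(pred)
  g <- as.integer(gt)
  structure(cpp_confusion(p, g), class = "confusion_counts")
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Derive the six evaluation metrics from confusion counts
#'
#' DSC = 2TP/(2TP+FN+FP), accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), PPV = TP/(TP+FP) and NPV = TN/(TN+FN), each
#' scaled to a percentage. A metric whose denominator is zero is undefined and
#' reported as `NA` (excluded from cohort aggregation), never as 0 or 100.
#'
#' @param counts A [confusion_counts()] object or named vector with `TP`,
#'   `TN`, `FP`, `FN`.
#' @return One-row tibble with the six metrics and the four counts.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]])
  total <- tp + tn + fp + fn
  if (total <= 0) stop("confusion counts are empty")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    dsc = ratio(2 * tp, 2 * tp + fn + fp),
    accuracy = ratio(tp + tn, total),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    TP = tp, TN = tn, FP = fp, FN = fn
  )
}

#' Evaluate a predicted mask against ground truth
#'
#' @param pred,gt Binary arrays of identical shape.
#' @return One-row tibble as from [compute_metrics()].
#' @export
evaluate_masks <- function(pred, gt) {
  compute_metrics(confusion_counts(pred, gt))
}

#' Aggregate per-patient metric reports into a cohort summary
#'
#' Mean and sample (n - 1) standard deviation of each metric across patients,
#' one report per patient per side; undefined (`NA`) entries are excluded from
#' that metric's aggregation.
#'
#' @param reports Tibble of per-patient rows containing the six metric
#'   columns (as from [compute_metrics()]).
#' @param side Optional label (`"medial"`/`"lateral"`) attached to the output.
#' @return Tibble with one row per metric: `metric`, `mean`, `sd`, `n_defined`
#'   and `side`.
#' @export
aggregate_cohort <- function(reports, side = NA_character_) {
  if (nrow(reports) < 2) stop("cohort summaries require at least 2 patients")
  purrr::map_dfr(METRIC_NAMES, function(m) {
    v <- reports[[m]]
    v <- v[!is.na(v)]
    tibble::tibble(metric = m,
                   mean = if (length(v) >= 1) mean(v) else NA_real_,
                   sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
                   n_defined = length(v),
                   side = side)
  })
}

#' Format a cohort summary in `mean (+/- sd)` style
#'
#' @param summary Tibble from [aggregate_cohort()].
#' @param digits Decimal places.
#' @return Tibble with a formatted `value` column per metric.
#' @export
format_cohort <- function(summary, digits = 2) {
  dplyr::mutate(summary,
                value = sprintf("%.*f (±%.*f)", digits, .data$mean,
                                digits, .data$sd))
}
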