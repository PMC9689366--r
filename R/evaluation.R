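#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @param mask_a,mask_b binary matrices of equal shape.
#' @return Dice score in \[0,1\].
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stopf("mask shape mismatch")
  sa <- sum(mask_a); sb <- sum(mask_b)
  if (sa + sb == 0) return(1)
  2 * sum(mask_a * mask_b) / (sa + sb)
}

# 1 - IoU distance; both-empty masks are at distance 0.
iou_distance <- function(a, b) {
  u <- sum(pmax(a, b))
  if (u == 0) return(0)
  1 - sum(a * b) / u
}

#' Growth-classification metrics
#'
#' Balanced accuracy `(TPR + TNR)/2`, precision and recall for binary growth
#' labels. Metrics with an empty denominator are returned as `NA`.
#'
#' @param predicted,true 0/1 vectors of equal length.
#' @return List with `bacc`, `precision`, `recall`.
#' @export
classification_metrics <- function(predicted, true) {
  if (length(predicted) != length(true)) stopf("label length mismatch")
  if (!all(predicted %in% 0:1) || !all(true %in% 0:1)) {
    stopf("labels must be 0/1")
  }
  tp <- sum(predicted == 1 & true == 1)
  fp <- sum(predicted == 1 & true == 0)
  tn <- sum(predicted == 0 & true == 0)
  fn <- sum(predicted == 0 & true == 1)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(bacc = mean(c(tpr, tnr)),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = tpr)
}

#' Generalized energy distance between segmentation sample sets
#'
#' Distribution distance between `n` generated and `m` reference
#' segmentations with the 1-IoU mask distance:
#' `D^2 = (2/nm) sum d(Y', Y) - (1/n^2) sum d(Y', Y') - (1/m^2) sum d(Y, Y)`.
#' Both-empty mask pairs are at distance 0.
#'
#' @param pred_samples list of binary prediction masks.
#' @param gt_masks list of binary reference masks.
#' @return List with `ged` (= `sqrt(max(0, D^2))`), `dged2`, and the
#'   components `two_cross`, `within_pred`, `within_gt`.
#' @export
ged <- function(pred_samples, gt_masks) {
  n <- length(pred_samples); m <- length(gt_masks)
  if (n < 1 || m < 1) stopf("need at least one mask on each side")
  cross <- 0
  for (a in pred_samples) for (b in gt_masks) cross <- cross + iou_distance(a, b)
  wp <- 0
  for (a in pred_samples) for (b in pred_samples) wp <- wp + iou_distance(a, b)
  wg <- 0
  for (a in gt_masks) for (b in gt_masks) wg <- wg + iou_distance(a, b)
  two_cross <- 2 * cross / (n * m)
  within_pred <- wp / n^2
  within_gt <- wg / m^2
  dged2 <- two_cross - within_pred - within_gt
  list(ged = sqrt(max(0, dged2)), dged2 = dged2, two_cross = two_cross,
       within_pred = within_pred, within_gt = within_gt)
}

#' Balanced accuracy at two standard deviations
#'
#' Judges each case by the interval `delta_mean +/- 2 * delta_std` against
#' the 2 mm growth threshold: a true positive needs both the reference growth
#' and the lower interval end above 2 mm; a true negative needs both the
#' reference growth and the upper interval end at or below 2 mm.
#'
#' @param estimates list of `growth_estimate` objects.
#' @param gt_growth_mm reference growth sizes (mm), one per estimate.
#' @return Balanced accuracy in \[0,1\].
#' @export
bacc_2std <- function(estimates, gt_growth_mm) {
  if (length(estimates) != length(gt_growth_mm)) stopf("length mismatch")
  lower <- vapply(estimates, function(e) e$delta_mean - 2 * e$delta_std,
                  numeric(1))
  upper <- vapply(estimates, function(e) e$delta_mean + 2 * e$delta_std,
                  numeric(1))
  pos <- gt_growth_mm > 2
  tp <- sum(pos & lower > 2)
  fn <- sum(pos & lower <= 2)
  tn <- sum(!pos & upper <= 2)
  fp <- sum(!pos & upper > 2)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  # one-sided cohorts reduce to the defined rate
  mean(c(tpr, tnr), na.rm = TRUE)
}

#' Closest annotator by growth size (Mahalanobis)
#'
#' Selects the annotator whose growth measurement is nearest the predicted
#' growth distribution: argmin of `|g - delta_mean| / delta_std` (falling
#' back to the absolute difference when `delta_std` is 0). Ties go to the
#' lowest index.
#'
#' @param estimate a `growth_estimate`.
#' @param annotator_growth_mm per-annotator growth sizes (mm).
#' @return Index into `annotator_growth_mm`.
#' @export
closest_annotator_growth <- function(estimate, annotator_growth_mm) {
  if (!length(annotator_growth_mm)) stopf("no annotators supplied")
  d <- abs(annotator_growth_mm - estimate$delta_mean)
  if (estimate$delta_std > 0) d <- d / estimate$delta_std
  which.min(d)
}

#' Closest annotator by segmentation (mean Dice)
#'
#' Selects the annotator whose reference mask has the highest mean Dice
#' against the generated segmentation samples. Ties go to the lowest index.
#'
#' @param pred_samples list of binary sample masks.
#' @param gt_masks list of per-annotator reference masks.
#' @return Index into `gt_masks`.
#' @export
closest_annotator_segmentation <- function(pred_samples, gt_masks) {
  if (!length(pred_samples) || !length(gt_masks)) stopf("empty inputs")
  scores <- vapply(gt_masks, function(gt) {
    mean(vapply(pred_samples, function(s) dice(s, gt), numeric(1)))
  }, numeric(1))
  which.max(scores)
}

#' Mean absolute error of predicted growth sizes
#'
#' @param estimates list of `growth_estimate` objects (or a numeric vector of
#'   predicted growths).
#' @param gt_growth_mm reference growth sizes (mm).
#' @return MAE in mm.
#' @export
mae_growth <- function(estimates, gt_growth_mm) {
  pred <- if (is.numeric(estimates)) estimates else {
    vapply(estimates, `[[`, numeric(1), "delta_mean")
  }
  if (length(pred) != length(gt_growth_mm) || !length(pred)) {
    stopf("need matched, non-empty growth vectors")
  }
  mean(abs(pred - gt_growth_mm))
}

growth_bins <- c(-Inf, 0, 2, 5, Inf)
growth_bin_labels <- c("<=0mm", "(0,2]mm", "(2,5]mm", ">5mm")
time_bin_labels <- c("<=6mo", "(6,12]mo", "(12,24]mo", ">24mo")

#' Accuracy stratified by growth size and time to predict
#'
#' Cross-tabulates classification accuracy over growth bins (<=0, (0,2],
#' (2,5], >5 mm of reference growth) and time bins (up to 6, 12, 24, more
#' than 24 months), plus the aggregate accuracy excluding the most distant
#' (>24 months) predictions. Empty cells are `NA`.
#'
#' @param estimates list of `growth_estimate` objects.
#' @param records list of matching [growth_record()] objects (supply the
#'   reference growth, elapsed time and label).
#' @return List with matrices `accuracy` and `fraction` (4x4,
#'   growth x time), and scalar `accuracy_within_24mo`.
#' @export
stratified_report <- function(estimates, records) {
  if (length(estimates) != length(records)) stopf("length mismatch")
  n <- length(estimates)
  pred <- vapply(estimates, classify_growth, integer(1))
  truth <- vapply(records, `[[`, integer(1), "growth_label")
  gsize <- vapply(records, function(r) r$d1_mm - r$d0_mm, numeric(1))
  tbin <- findInterval(vapply(records, `[[`, integer(1), "elapsed_days"),
                       c(184, 366, 731)) + 1L
  gbin <- findInterval(gsize, growth_bins[-1], left.open = TRUE) + 1L
  acc <- frac <- matrix(NA_real_, 4, 4,
                        dimnames = list(growth_bin_labels, time_bin_labels))
  for (gi in 1:4) for (ti in 1:4) {
    sel <- gbin == gi & tbin == ti
    if (any(sel)) {
      acc[gi, ti] <- mean(pred[sel] == truth[sel])
      frac[gi, ti] <- sum(sel) / n
    }
  }
  near <- tbin < 4L
  list(accuracy = acc, fraction = frac,
       accuracy_within_24mo = if (any(near)) {
         mean(pred[near] == truth[near])
       } else NA_real_)
}
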