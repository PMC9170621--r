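#' Tritan to red-green threshold ratio
#'
#' The classification metric: the minimum of the tritan:protan and
#' tritan:deutan threshold ratios. Non-visual factors (attention, lapses,
#' motivation) inflate thresholds on all three axes alike and cancel in the
#' ratio, while a selective red-green deficit drives it down. Congenital
#' tritan deficiencies are rare enough that an elevated tritan threshold
#' masking a red-green deficit is not a practical concern.
#'
#' @param thresholds named numeric with entries `protan`, `deutan`,
#'   `tritan`, all positive. Ceiling-flagged (unresolved) thresholds should
#'   enter at the 0.9 ceiling.
#' @return Unitless ratio `min(tritan/protan, tritan/deutan)`.
#' @export
threshold_ratio <- function(thresholds) {
  stopifnot(all(cvd_axes() %in% names(thresholds)))
  t3 <- as.numeric(thresholds[cvd_axes()])
  if (any(!is.finite(t3)) || any(t3 <= 0)) {
    stop("invalid-threshold: thresholds must be positive and finite")
  }
  min(t3[3] / t3[1], t3[3] / t3[2])
}

#' Classify a threshold ratio
#'
#' @param ratio positive threshold ratio from [threshold_ratio()].
#' @param criterion criterion ratio; default 0.59.
#' @return `"CVD"` if `ratio < criterion`, otherwise `"normal"` (the
#'   boundary itself classifies as normal).
#' @export
classify_ratio <- function(ratio, criterion = 0.59) {
  stopifnot(is.finite(ratio), ratio > 0, is.finite(criterion), criterion > 0)
  if (ratio < criterion) "CVD" else "normal"
}

#' Derive the criterion ratio from a discovery cohort
#'
#' The criterion is placed halfway between the largest threshold ratio in
#' the CVD group and the smallest in the control group. If the groups
#' overlap the midpoint is still returned, with a warning.
#'
#' @param cvd_ratios,control_ratios nonempty numeric vectors of threshold
#'   ratios for the two reference groups.
#' @return The criterion ratio.
#' @export
derive_criterion <- function(cvd_ratios, control_ratios) {
  stopifnot(length(cvd_ratios) > 0, length(control_ratios) > 0,
            all(is.finite(cvd_ratios)), all(is.finite(control_ratios)))
  hi_cvd <- max(cvd_ratios)
  lo_ctrl <- min(control_ratios)
  if (hi_cvd >= lo_ctrl) {
    warning("derive_criterion: groups overlap (max CVD ratio ", signif(hi_cvd, 4),
            " >= min control ratio ", signif(lo_ctrl, 4),
            "); returning the midpoint anyway")
  }
  (hi_cvd + lo_ctrl) / 2
}

#' Reference grouping by pseudoisochromatic plate errors
#'
#' Maps an error count on the reference plate test to the study grouping:
#' no errors is control, one or two errors is inconclusive, three or more
#' is CVD.
#'
#' @param errors nonnegative integer error count (vectorised).
#' @return Character vector in `{"control", "inconclusive", "CVD"}`.
#' @export
ishihara_group <- function(errors) {
  if (any(!is.finite(errors)) || any(errors < 0)) {
    stop("invalid-count: error counts must be nonnegative")
  }
  ifelse(errors == 0, "control", ifelse(errors <= 2, "inconclusive", "CVD"))
}

#' Diagnostic accuracy of predicted labels against a reference
#'
#' @param predicted character vector of `"CVD"`/`"normal"` predictions.
#' @param reference equal-length character vector of reference labels in
#'   `{"CVD", "normal", "control", "inconclusive"}`; `"control"` is treated
#'   as `"normal"`, and inconclusive references are excluded from the
#'   metrics (their count is reported).
#' @return List with `sensitivity` (TP/(TP+FN)), `specificity`
#'   (TN/(TN+FP)), the confusion counts `tp`, `fp`, `tn`, `fn`, and
#'   `n_inconclusive`. A rate whose reference class is empty is `NA` with a
#'   warning (`undefined-metric`).
#' @export
confusion_metrics <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  reference <- ifelse(reference == "control", "normal", reference)
  keep <- reference != "inconclusive"
  n_inc <- sum(!keep)
  predicted <- predicted[keep]
  reference <- reference[keep]
  stopifnot(all(predicted %in% c("CVD", "normal")),
            all(reference %in% c("CVD", "normal")))
  tp <- sum(predicted == "CVD" & reference == "CVD")
  fn <- sum(predicted == "normal" & reference == "CVD")
  tn <- sum(predicted == "normal" & reference == "normal")
  fp <- sum(predicted == "CVD" & reference == "normal")
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("undefined-metric: no CVD references; sensitivity is NA")
    NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("undefined-metric: no normal references; specificity is NA")
    NA_real_
  }
  list(sensitivity = sens, specificity = spec,
       tp = tp, fp = fp, tn = tn, fn = fn, n_inconclusive = n_inc)
}

#' Bootstrap power for sensitivity and specificity targets
#'
#' A best-effort reconstruction of a design-stage power computation: each
#' replicate draws the number of correctly classified positives (and
#' negatives) as a binomial at the assumed true rate, and power is the
#' fraction of replicates whose estimated rate falls within the stated
#' half-range of the truth. This is an interpretation of the original
#' procedure, not a reproduction of it.
#'
#' @param n_cvd,n_control group sizes.
#' @param true_sens,true_spec assumed true rates, in (0, 1].
#' @param half_range_sens,half_range_spec acceptable absolute deviation of
#'   the estimated rate from the truth.
#' @param reps bootstrap replicates.
#' @param seed RNG seed.
#' @return List with `power_sens` and `power_spec`.
#' @export
power_bootstrap <- function(n_cvd, n_control, true_sens, true_spec,
                            half_range_sens, half_range_spec,
                            reps = 10000L, seed = NULL) {
  stopifnot(n_cvd > 0, n_control > 0,
            true_sens > 0, true_sens <= 1, true_spec > 0, true_spec <= 1)
  .with_seed(seed, {
    sens_hat <- stats::rbinom(reps, n_cvd, true_sens) / n_cvd
    spec_hat <- stats::rbinom(reps, n_control, true_spec) / n_control
    list(power_sens = mean(abs(sens_hat - true_sens) <= half_range_sens),
         power_spec = mean(abs(spec_hat - true_spec) <= half_range_spec))
  })
}
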