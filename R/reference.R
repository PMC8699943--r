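#' Classify hepatic steatosis from a CAP measurement
#'
#' The controlled attenuation parameter (CAP, dB/m) from transient
#' elastography quantifies liver fat; values at or above the threshold
#' define steatosis (boundary inclusive: a reading exactly at the threshold
#' is positive).
#'
#' @param cap CAP value(s), dB/m. `NA` yields `NA` (subject has no CAP
#'   label and is dropped from CAP-referenced analyses).
#' @param threshold steatosis threshold, dB/m (default 248).
#' @return logical vector.
#' @export
classify_cap_steatosis <- function(cap, threshold = 248) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  as.numeric(cap) >= threshold
}

#' Liver stiffness measurement reliability
#'
#' An LSM session is reliable when at least `min_valid` valid measurements
#' were obtained and either the IQR/median of the measurements is below
#' `iqr_ratio_max` or the median stiffness is below `median_max` kPa
#' (low-stiffness readings are robust to spread).
#'
#' @param lsm_n_valid number of valid measurements.
#' @param lsm_iqr_over_median IQR divided by median (dimensionless).
#' @param lsm_median median stiffness, kPa.
#' @param min_valid minimum valid measurement count (default 10).
#' @param iqr_ratio_max IQR/median bound, strict (default 0.3).
#' @param median_max stiffness bound, strict (default 7.1 kPa).
#' @return logical vector; `NA` where inputs are missing.
#' @export
lsm_reliable <- function(lsm_n_valid, lsm_iqr_over_median, lsm_median,
                         min_valid = 10, iqr_ratio_max = 0.3,
                         median_max = 7.1) {
  (lsm_n_valid >= min_valid) &
    ((lsm_iqr_over_median < iqr_ratio_max) | (lsm_median < median_max))
}

#' Build a binary steatosis reference standard for a cohort
#'
#' Constructs the label vector the accuracy analyses score against, from
#' either the radiologist ultrasound diagnosis (`reference = "us"`, consumed
#' as a supplied label, never recomputed) or the CAP rule
#' (`reference = "cap"`, positive iff CAP >= `cap_threshold`). Subjects
#' lacking the chosen reference are excluded from the label vector and
#' counted. When `require_reliable_lsm = TRUE` the CAP reference
#' additionally drops subjects failing [lsm_reliable()]; by default the
#' reliability predicate is computed and reported but does not gate.
#'
#' @param cohort cohort tibble.
#' @param reference `"us"` or `"cap"`.
#' @param cap_threshold CAP steatosis threshold, dB/m (default 248).
#' @param require_reliable_lsm gate CAP labels on LSM reliability
#'   (default `FALSE`).
#' @return list with:
#'   * `labels` — logical vector, one per retained subject;
#'   * `index` — row indices of the cohort the labels align with;
#'   * `n_dropped` — subjects without the reference (plus, when gating,
#'     unreliable LSM sessions);
#'   * `n_unreliable_lsm` — count failing the reliability predicate
#'     (informational);
#'   * `prevalence` — mean of `labels`.
#' @export
build_reference_labels <- function(cohort, reference = c("us", "cap"),
                                   cap_threshold = 248,
                                   require_reliable_lsm = FALSE) {
  reference <- match.arg(reference)
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("build_reference_labels: empty cohort", call. = FALSE)
  if (reference == "us") {
    lab <- cohort$us_steatosis
    keep <- !is.na(lab)
  } else {
    lab <- classify_cap_steatosis(cohort$cap, threshold = cap_threshold)
    keep <- !is.na(lab)
    if (require_reliable_lsm) {
      rel <- lsm_reliable(cohort$lsm_n_valid, cohort$lsm_iqr_over_median,
                          cohort$lsm_median)
      keep <- keep & !is.na(rel) & rel
    }
  }
  if (!any(keep)) {
    stop("build_reference_labels: no subject carries the '", reference,
         "' reference", call. = FALSE)
  }
  rel_all <- lsm_reliable(cohort$lsm_n_valid, cohort$lsm_iqr_over_median,
                          cohort$lsm_median)
  list(labels = lab[keep],
       index = which(keep),
       n_dropped = sum(!keep),
       n_unreliable_lsm = sum(!rel_all, na.rm = TRUE),
       prevalence = mean(lab[keep]))
}
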