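#' Compute the fatty liver index (FLI)
#'
#' The FLI is a logistic-form score on the open interval (0, 100) built from
#' serum triglycerides, body mass index, gamma glutamyl transpeptidase and
#' waist circumference:
#'
#' \deqn{FLI = 100 \cdot \sigma(0.953\,\ln TG + 0.139\,BMI + 0.718\,\ln GGT
#'   + 0.053\,WC - 15.745)}
#'
#' where \eqn{\sigma} is the standard logistic function and logarithms are
#' natural. Higher values indicate a higher probability of hepatic steatosis.
#' All four coefficients are positive, so the score is strictly increasing in
#' each input.
#'
#' @param tg serum triglycerides, mg/dL (must be > 0; the formula takes its
#'   logarithm).
#' @param bmi body mass index, kg/m^2 (> 0).
#' @param ggt gamma glutamyl transpeptidase, IU/L (> 0).
#' @param wc waist circumference, cm (> 0).
#'
#' @details Inputs are vectorized and recycled by the usual rules. `NA`
#'   inputs propagate to `NA` scores; non-positive `tg` or `ggt` (for which
#'   the logarithm is undefined) or non-positive `bmi`/`wc` raise an error
#'   rather than returning a silent `NaN`.
#'
#' @return numeric vector of FLI scores, in (0, 100), at full floating
#'   precision (round only at report time).
#'
#' @examples
#' compute_fli(tg = 100, bmi = 25, ggt = 30, wc = 90)  # ~33.9
#' @export
compute_fli <- function(tg, bmi, ggt, wc) {
  n <- max(length(tg), length(bmi), length(ggt), length(wc))
  tg <- rep_len(as.numeric(tg), n)
  bmi <- rep_len(as.numeric(bmi), n)
  ggt <- rep_len(as.numeric(ggt), n)
  wc <- rep_len(as.numeric(wc), n)
  bad <- function(x) !is.na(x) & x <= 0
  if (any(bad(tg)) || any(bad(ggt))) {
    stop("compute_fli: tg and ggt must be positive (log-transformed in the index)",
         call. = FALSE)
  }
  if (any(bad(bmi)) || any(bad(wc))) {
    stop("compute_fli: bmi and wc must be positive", call. = FALSE)
  }
  L <- 0.953 * log(tg) + 0.139 * bmi + 0.718 * log(ggt) + 0.053 * wc - 15.745
  100 * plogis(L)
}

#' Add FLI and GFR columns to a cohort table
#'
#' Convenience wrapper appending `fli` (and `gfr` when creatinine and age are
#' available) to a cohort tibble. Rows with any missing FLI input get `NA`.
#'
#' @param cohort a cohort tibble (see [read_cohort()]).
#' @return the cohort with an `fli` column and, when possible, a `gfr`
#'   column appended.
#' @export
add_indices <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  need <- c("tg", "bmi", "ggt", "wc")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("add_indices: cohort lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok <- complete.cases(cohort[need]) &
    cohort$tg > 0 & cohort$ggt > 0 & cohort$bmi > 0 & cohort$wc > 0
  ok[is.na(ok)] <- FALSE
  fli <- rep(NA_real_, nrow(cohort))
  if (any(ok)) {
    fli[ok] <- compute_fli(cohort$tg[ok], cohort$bmi[ok],
                           cohort$ggt[ok], cohort$wc[ok])
  }
  cohort$fli <- fli
  if (all(c("creatinine", "age", "sex") %in% names(cohort))) {
    gok <- !is.na(cohort$creatinine) & !is.na(cohort$age) &
      !is.na(cohort$sex) & cohort$creatinine > 0 & cohort$age > 0
    gfr <- rep(NA_real_, nrow(cohort))
    if (any(gok)) {
      gfr[gok] <- compute_gfr_mdrd(cohort$creatinine[gok], cohort$age[gok],
                                   cohort$sex[gok])
    }
    cohort$gfr <- gfr
  }
  cohort
}

#' Estimated glomerular filtration rate (4-variable MDRD)
#'
#' IDMS-traceable 4-variable MDRD study equation:
#' \deqn{GFR = 175 \cdot S_{cr}^{-1.154} \cdot age^{-0.203} \cdot 0.742\,[if\ female]}
#' in mL/min/1.73 m^2. The ethnicity coefficient is omitted (intended for
#' ethnically homogeneous checkup populations); the estimate is descriptive
#' and feeds no downstream classification in this package.
#'
#' @param creatinine serum creatinine, mg/dL (> 0).
#' @param age age in years (> 0).
#' @param sex `"male"` or `"female"` (vectorized).
#' @return numeric vector of eGFR values.
#' @examples
#' compute_gfr_mdrd(1.0, 50, "male")   # ~79.1
#' compute_gfr_mdrd(1.0, 50, "female") # lower by the 0.742 factor
#' @export
compute_gfr_mdrd <- function(creatinine, age, sex) {
  n <- max(length(creatinine), length(age), length(sex))
  creatinine <- rep_len(as.numeric(creatinine), n)
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(as.character(sex), n)
  if (any(!is.na(creatinine) & creatinine <= 0) ||
      any(!is.na(age) & age <= 0)) {
    stop("compute_gfr_mdrd: creatinine and age must be positive", call. = FALSE)
  }
  if (!all(is.na(sex) | sex %in% c("male", "female"))) {
    stop("compute_gfr_mdrd: sex must be 'male' or 'female'", call. = FALSE)
  }
  gfr <- 175 * creatinine^(-1.154) * age^(-0.203)
  gfr[!is.na(sex) & sex == "female"] <- gfr[!is.na(sex) & sex == "female"] * 0.742
  gfr[is.na(sex)] <- NA_real_
  gfr
}
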