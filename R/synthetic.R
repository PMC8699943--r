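#' Log-normal parameters from a median and quartiles
#'
#' Right-skewed checkup variables (triglycerides, CAP) are usually reported
#' as median (Q1, Q3). Fitting a log-normal through those three quantiles
#' gives `mu = ln(median)` and `sigma = (ln Q3 - ln Q1) / (2 z_{0.75})`,
#' with `z_{0.75}` the standard-normal upper-quartile deviate. The implied
#' distribution reproduces the median exactly and the quartiles exactly
#' when they are symmetric on the log scale (Q1 Q3 = median^2), otherwise
#' on average.
#'
#' @param median,q1,q3 the reported quantiles, with 0 < q1 < median < q3.
#' @return named numeric vector `c(mu, sigma)` (log-scale parameters).
#' @export
lognormal_from_median_iqr <- function(median, q1, q3) {
  if (!(q1 > 0 && q1 < median && median < q3)) {
    stop("lognormal_from_median_iqr: need 0 < q1 < median < q3", call. = FALSE)
  }
  z75 <- qnorm(0.75)
  c(mu = log(median), sigma = (log(q3) - log(q1)) / (2 * z75))
}

#' Log-normal parameters from a mean and standard deviation
#'
#' Moment-matched log-normal: `sigma^2 = ln(1 + sd^2/mean^2)`,
#' `mu = ln(mean) - sigma^2/2`; the implied mean and SD reproduce the
#' inputs exactly. Used for strongly right-skewed variables reported as
#' mean +/- SD (GGT).
#'
#' @param mean,sd the reported moments, both > 0.
#' @return named numeric vector `c(mu, sigma)`.
#' @export
lognormal_from_mean_sd <- function(mean, sd) {
  if (!(mean > 0 && sd > 0)) {
    stop("lognormal_from_mean_sd: mean and sd must be positive", call. = FALSE)
  }
  s2 <- log(1 + sd^2 / mean^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Default stratum parameters for the synthetic checkup cohort
#'
#' Distributional parameters for the four (sex x ultrasound-steatosis)
#' strata of an asymptomatic Korean health-checkup population, taken from
#' published summary statistics of such a cohort: means and SDs for
#' approximately symmetric variables (age, BMI, waist circumference, blood
#' pressures, AST, ALT), mean/SD log-normal fits for GGT, and median/IQR
#' log-normal fits for triglycerides and CAP, plus comorbidity prevalences.
#'
#' @return nested list: `$male$nafld`, `$male$no_nafld`, `$female$nafld`,
#'   `$female$no_nafld`. Each stratum holds `normal` (named list of
#'   `c(mean, sd)`), `lognormal_meansd` (GGT), `lognormal_quartiles`
#'   (tg, cap as `c(median, q1, q3)`), `p_diabetes`, `p_hypertension`, `n`.
#' @export
default_cohort_params <- function() {
  st <- function(age, bmi, wc, sbp, dbp, ast, alt, ggt, tg, cap,
                 p_dm, p_htn, n) {
    list(normal = list(age = age, bmi = bmi, wc = wc, sbp = sbp, dbp = dbp,
                       ast = ast, alt = alt),
         lognormal_meansd = list(ggt = ggt),
         lognormal_quartiles = list(tg = tg, cap = cap),
         p_diabetes = p_dm, p_hypertension = p_htn, n = n)
  }
  list(
    male = list(
      no_nafld = st(age = c(55.5, 11.6), bmi = c(23.3, 2.5), wc = c(85.8, 7.3),
                    sbp = c(120.9, 14.0), dbp = c(79.2, 10.2),
                    ast = c(26.2, 11.5), alt = c(27.7, 20.0),
                    ggt = c(30.0, 27.5),
                    tg = c(83, 62, 114), cap = c(224, 200, 248),
                    p_dm = 0.094, p_htn = 0.208, n = 1187),
      nafld = st(age = c(54.4, 9.7), bmi = c(25.9, 3.0), wc = c(92.8, 7.8),
                 sbp = c(120.5, 13.8), dbp = c(79.8, 10.4),
                 ast = c(28.6, 13.7), alt = c(33.3, 23.3),
                 ggt = c(41.4, 33.1),
                 tg = c(128, 92, 177), cap = c(278, 247, 309),
                 p_dm = 0.178, p_htn = 0.207, n = 2162)),
    female = list(
      no_nafld = st(age = c(53.8, 10.6), bmi = c(22.3, 2.7), wc = c(79.1, 7.6),
                    sbp = c(120.1, 14.4), dbp = c(80.0, 9.5),
                    ast = c(24.5, 11.2), alt = c(27.5, 23.3),
                    ggt = c(19.3, 12.0),
                    tg = c(67, 49, 88.5), cap = c(213, 189, 240),
                    p_dm = 0.033, p_htn = 0.217, n = 360),
      nafld = st(age = c(57.6, 9.1), bmi = c(24.9, 3.4), wc = c(88.1, 8.4),
                 sbp = c(121.6, 14.7), dbp = c(81.0, 10.2),
                 ast = c(26.7, 13.6), alt = c(29.3, 18.0),
                 ggt = c(30.5, 36.4),
                 tg = c(112, 78, 152), cap = c(283, 256, 319),
                 p_dm = 0.189, p_htn = 0.239, n = 301)))
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the composition of the reference checkup population:
#' 4009 subjects, 83.5% male, ultrasound-steatosis prevalence 2162/3349 in
#' males and 301/661 in females. The published source provides marginal
#' distributions only, so the inter-variable dependence is an explicit,
#' documented knob: a Gaussian copula with pairwise correlation `rho_fli`
#' among the FLI inputs (bmi, wc, tg, ggt) and `rho_cap` between CAP and
#' each FLI input, conditional on stratum.
#'
#' @param n_total number of subjects.
#' @param male_fraction proportion male.
#' @param prevalence_male,prevalence_female per-sex ultrasound-steatosis
#'   prevalence.
#' @param rho_fli copula correlation among bmi, wc, tg, ggt (default 0.3).
#' @param rho_cap copula correlation of cap with each FLI input
#'   (default 0.2).
#' @param seed integer master seed; the whole generation is a deterministic
#'   function of it (per-stratum substreams are derived from it).
#' @param params stratum parameters (default [default_cohort_params()]).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_total = 4009, male_fraction = 0.835,
                             prevalence_male = 2162 / 3349,
                             prevalence_female = 301 / 661,
                             rho_fli = 0.3, rho_cap = 0.2,
                             seed = 1L,
                             params = default_cohort_params()) {
  stopifnot(n_total >= 0, male_fraction >= 0, male_fraction <= 1,
            prevalence_male >= 0, prevalence_male <= 1,
            prevalence_female >= 0, prevalence_female <= 1)
  R <- copula_matrix(rho_fli, rho_cap)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("synthetic_config: copula correlation matrix is not positive definite",
         call. = FALSE)
  }
  structure(list(n_total = as.integer(n_total),
                 male_fraction = male_fraction,
                 prevalence_male = prevalence_male,
                 prevalence_female = prevalence_female,
                 rho_fli = rho_fli, rho_cap = rho_cap,
                 seed = as.integer(seed), params = params),
            class = "synthetic_config")
}

# Correlation matrix over (bmi, wc, tg, ggt, cap) for the Gaussian copula.
copula_matrix <- function(rho_fli, rho_cap) {
  vars <- c("bmi", "wc", "tg", "ggt", "cap")
  R <- diag(5)
  R[1:4, 1:4][upper.tri(R[1:4, 1:4])] <- rho_fli
  R[1:4, 1:4][lower.tri(R[1:4, 1:4])] <- rho_fli
  R[5, 1:4] <- rho_cap
  R[1:4, 5] <- rho_cap
  dimnames(R) <- list(vars, vars)
  R
}

# Draw one stratum's subjects: Gaussian copula over (bmi, wc, tg, ggt, cap),
# independent draws for the remaining variables, physiologic floors enforced
# by redrawing violating rows (floors sit far in the tails, so redraw mass
# and marginal distortion are negligible).
draw_stratum <- function(n, sex, status, stratum, R, seed) {
  if (n == 0L) return(NULL)
  withr::with_seed(seed, {
    L <- chol(R)
    floors <- c(bmi = 12, wc = 40, tg = 1, ggt = 1, cap = -Inf)
    caps_hi <- c(bmi = Inf, wc = Inf, tg = Inf, ggt = Inf, cap = Inf)
    tg_par <- lognormal_from_median_iqr(stratum$lognormal_quartiles$tg[1],
                                        stratum$lognormal_quartiles$tg[2],
                                        stratum$lognormal_quartiles$tg[3])
    cap_par <- lognormal_from_median_iqr(stratum$lognormal_quartiles$cap[1],
                                         stratum$lognormal_quartiles$cap[2],
                                         stratum$lognormal_quartiles$cap[3])
    ggt_par <- lognormal_from_mean_sd(stratum$lognormal_meansd$ggt[1],
                                      stratum$lognormal_meansd$ggt[2])
    draw_block <- function(m) {
      z <- matrix(rnorm(m * 5), m, 5) %*% L
      u <- pnorm(z)
      cbind(bmi = qnorm(u[, 1], stratum$normal$bmi[1], stratum$normal$bmi[2]),
            wc = qnorm(u[, 2], stratum$normal$wc[1], stratum$normal$wc[2]),
            tg = qlnorm(u[, 3], tg_par["mu"], tg_par["sigma"]),
            ggt = qlnorm(u[, 4], ggt_par["mu"], ggt_par["sigma"]),
            cap = qlnorm(u[, 5], cap_par["mu"], cap_par["sigma"]))
    }
    x <- draw_block(n)
    repeat {
      bad <- rowSums(sweep(x, 2, floors, "<") |
                       sweep(x, 2, caps_hi, ">")) > 0
      if (!any(bad)) break
      x[bad, ] <- draw_block(sum(bad))[, , drop = FALSE]
    }
    # winsorize CAP to the device reporting range: preserves the median and
    # quartiles exactly (the clamp sits in the far tails) while keeping
    # every record inside the ingestion plausibility window
    x[, "cap"] <- pmin(pmax(x[, "cap"], 100), 400)
    rnorm_floor <- function(m, mean, sd, floor) {
      v <- rnorm(m, mean, sd)
      while (any(v < floor)) {
        v[v < floor] <- rnorm(sum(v < floor), mean, sd)
      }
      v
    }
    age <- rnorm_floor(n, stratum$normal$age[1], stratum$normal$age[2], 19)
    sbp <- rnorm_floor(n, stratum$normal$sbp[1], stratum$normal$sbp[2], 60)
    dbp <- rnorm_floor(n, stratum$normal$dbp[1], stratum$normal$dbp[2], 35)
    ast <- rnorm_floor(n, stratum$normal$ast[1], stratum$normal$ast[2], 5)
    alt <- rnorm_floor(n, stratum$normal$alt[1], stratum$normal$alt[2], 3)
    glucose <- rnorm_floor(n, 100, 12, 50)
    creat <- if (sex == "male") rnorm_floor(n, 0.95, 0.15, 0.3)
             else rnorm_floor(n, 0.75, 0.12, 0.3)
    # comorbidity flags are descriptive only: treatment indicators drawn so
    # the derived prevalences land near the stratum targets once the blood
    # pressure / glucose criteria contribute their share
    on_glc <- runif(n) < 0.8 * stratum$p_diabetes
    on_aht <- runif(n) < 0.5 * stratum$p_hypertension
    alc_max <- if (sex == "male") 20 else 10
    tibble::tibble(
      sex = sex,
      age = age, bmi = x[, "bmi"], wc = x[, "wc"],
      sbp = sbp, dbp = dbp, fasting_glucose = glucose,
      tg = x[, "tg"], ast = ast, alt = alt, ggt = x[, "ggt"],
      creatinine = creat,
      alcohol = runif(n, 0, 0.9 * alc_max),
      hbv_positive = FALSE, hcv_positive = FALSE,
      on_antihypertensives = on_aht, on_glucose_lowering = on_glc,
      us_steatosis = status == "nafld",
      cap = x[, "cap"],
      lsm_median = qlnorm(runif(n), log(4.5), 0.35),
      lsm_iqr_over_median = runif(n, 0.05, 0.28),
      lsm_n_valid = 10)
  })
}

#' Generate a synthetic health-checkup cohort
#'
#' Draws sex and ultrasound-steatosis status per subject from the
#' configured composition, then fills each (sex x status) stratum from its
#' marginal distributions joined by a Gaussian copula over (bmi, wc, tg,
#' ggt, cap). The ultrasound label is the latent stratum assignment itself
#' (the generator's ground truth); CAP-defined steatosis arises implicitly
#' when the drawn CAP crosses the 248 dB/m rule, so the two reference
#' standards are imperfectly concordant, as in real checkup data. Alcohol
#' and serology fields are set to pass the exclusion cascade. The output is
#' a deterministic function of `config$seed` (per-stratum substreams keep
#' each stratum reproducible when the others change).
#'
#' @param config a [synthetic_config()].
#' @return cohort tibble in the schema of [read_cohort()].
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_total
  if (n == 0L) return(empty_cohort())
  R <- copula_matrix(config$rho_fli, config$rho_cap)
  assign <- withr::with_seed(config$seed, {
    sex <- ifelse(runif(n) < config$male_fraction, "male", "female")
    prev <- ifelse(sex == "male", config$prevalence_male,
                   config$prevalence_female)
    status <- ifelse(runif(n) < prev, "nafld", "no_nafld")
    list(sex = sex, status = status)
  })
  pieces <- list()
  combos <- expand.grid(sex = c("male", "female"),
                        status = c("no_nafld", "nafld"),
                        stringsAsFactors = FALSE)
  filled <- vector("list", n)
  for (i in seq_len(nrow(combos))) {
    sx <- combos$sex[i]; stt <- combos$status[i]
    idx <- which(assign$sex == sx & assign$status == stt)
    # substream seeds derived from the master seed, kept under 2^31
    sub_seed <- (config$seed * 11L + i * 7919L) %% .Machine$integer.max
    piece <- draw_stratum(length(idx), sx, stt,
                          config$params[[sx]][[stt]], R, sub_seed)
    if (!is.null(piece)) {
      piece$subject_id <- sprintf("S%05d", idx)
      piece$.row <- idx
      pieces[[i]] <- piece
    }
  }
  cohort <- dplyr::bind_rows(pieces)
  cohort <- cohort[order(cohort$.row), , drop = FALSE]
  cohort$.row <- NULL
  cohort <- cohort[, names(cohort_schema()), drop = FALSE]
  tibble::as_tibble(cohort)
}
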