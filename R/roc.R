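#' Confusion counts at a single cutoff
#'
#' Test-positive is `score >= cutoff` (the score is a rule-in index:
#' high values predict disease).
#'
#' @param scores numeric vector of index scores.
#' @param labels logical vector of reference labels, same length.
#' @param cutoff scalar cutoff.
#' @return named list (class `confusion_counts`): tp, fp, tn, fn.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  check_scores_labels(scores, labels)
  stopifnot(length(cutoff) == 1L, is.finite(cutoff) || is.infinite(cutoff))
  pos <- scores >= cutoff
  structure(list(tp = sum(pos & labels), fp = sum(pos & !labels),
                 tn = sum(!pos & !labels), fn = sum(!pos & labels)),
            class = "confusion_counts")
}

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must be complete (drop missing upstream)",
         call. = FALSE)
  }
  if (!any(labels) || all(labels)) {
    stop("degenerate input: labels contain a single class", call. = FALSE)
  }
  invisible(TRUE)
}

#' Diagnostic accuracy metrics from confusion counts
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), predictive values,
#' likelihood ratios and Youden's J = se + sp - 1. A perfect specificity
#' makes the positive likelihood ratio infinite: it is carried as `Inf`
#' with the flag `plr_infinite`, never as a capped number. Predictive
#' values with a zero denominator are `NA` (undefined-marked).
#'
#' @param counts a `confusion_counts` object or list with tp/fp/tn/fn.
#' @param cutoff optional cutoff to record in the output row.
#' @return one-row tibble: cutoff, tp, fp, tn, fn, se, sp, ppv, npv,
#'   plr, nlr, youden_j, plr_infinite.
#' @export
metrics_from_counts <- function(counts, cutoff = NA_real_) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  if (tp + fn == 0 || tn + fp == 0) {
    stop("degenerate input: need at least one positive and one negative",
         call. = FALSE)
  }
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  plr_inf <- sp == 1
  plr <- if (plr_inf) Inf else se / (1 - sp)
  nlr <- if (sp > 0) (1 - se) / sp else NA_real_
  tibble::tibble(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
                 se = se, sp = sp, ppv = ppv, npv = npv,
                 plr = plr, nlr = nlr, youden_j = se + sp - 1,
                 plr_infinite = plr_inf)
}

#' Metrics from published sensitivity/specificity and a prevalence
#'
#' Recovers likelihood ratios, Youden's J and prevalence-adjusted
#' predictive values from summary operating characteristics alone, via
#' Bayes' rule:
#' \deqn{PPV = \frac{se\,p}{se\,p + (1-sp)(1-p)}, \quad
#'       NPV = \frac{sp\,(1-p)}{(1-se)\,p + sp\,(1-p)}}
#' Useful for auditing printed report tables and for transporting a test's
#' operating point to a population with a different disease prevalence.
#'
#' @param se sensitivity, in \[0, 1\].
#' @param sp specificity, in \[0, 1\].
#' @param prevalence disease prevalence p, in \[0, 1\]; `NA` omits the
#'   predictive values.
#' @return one-row tibble: se, sp, ppv, npv, plr, nlr, youden_j,
#'   plr_infinite.
#' @export
metrics_from_rates <- function(se, sp, prevalence = NA_real_) {
  stopifnot(length(se) == 1L, length(sp) == 1L,
            se >= 0, se <= 1, sp >= 0, sp <= 1,
            is.na(prevalence) || (prevalence >= 0 && prevalence <= 1))
  plr_inf <- sp == 1
  plr <- if (plr_inf) Inf else se / (1 - sp)
  nlr <- if (sp > 0) (1 - se) / sp else NA_real_
  p <- prevalence
  if (is.na(p)) {
    ppv <- npv <- NA_real_
  } else {
    ppv_den <- se * p + (1 - sp) * (1 - p)
    npv_den <- (1 - se) * p + sp * (1 - p)
    ppv <- if (ppv_den > 0) se * p / ppv_den else NA_real_
    npv <- if (npv_den > 0) sp * (1 - p) / npv_den else NA_real_
  }
  tibble::tibble(se = se, sp = sp, ppv = ppv, npv = npv,
                 plr = plr, nlr = nlr, youden_j = se + sp - 1,
                 plr_infinite = plr_inf)
}

#' AUC by the Mann-Whitney estimator
#'
#' Probability that a randomly chosen diseased subject scores above a
#' randomly chosen non-diseased one, ties counted one half. Computed from
#' midranks in O(n log n); identical to the trapezoidal area under the
#' empirical ROC curve over all distinct cutoffs.
#'
#' @inheritParams confusion_at_cutoff
#' @return scalar AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong placement-value variance of the AUC estimator.
delong_var <- function(scores, labels) {
  x <- scores[labels]   # positives
  y <- scores[!labels]  # negatives
  m <- length(x); n <- length(y)
  # placement of each positive among negatives (and vice versa) via midranks
  all_r <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rx) / n          # per-positive placements
  v01 <- 1 - (all_r[m + seq_len(n)] - ry) / m  # per-negative placements
  var(v10) / m + var(v01) / n
}

#' Confidence interval for the AUC
#'
#' Two methods: `"delong"` — asymptotic normal interval with the DeLong
#' placement-value variance (deterministic, the standard for a single ROC
#' curve); `"bootstrap"` — percentile interval over stratified resamples
#' (positives and negatives resampled separately, so every resample keeps
#' both classes), deterministic given `seed`. Interval endpoints are
#' clipped to \[0, 1\].
#'
#' @inheritParams confusion_at_cutoff
#' @param method `"delong"` or `"bootstrap"`.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap replicates (default 2000; minimum 100).
#' @param seed integer seed for the bootstrap stream.
#' @return numeric vector `c(low, high)`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   level = 0.95, n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  check_scores_labels(scores, labels)
  stopifnot(level > 0, level < 1)
  auc <- auc_mann_whitney(scores, labels)
  if (method == "delong") {
    se_auc <- sqrt(delong_var(scores, labels))
    z <- qnorm(1 - (1 - level) / 2)
    ci <- c(auc - z * se_auc, auc + z * se_auc)
  } else {
    stopifnot(n_boot >= 100)
    pos <- scores[labels]
    neg <- scores[!labels]
    boots <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(i) {
        bs <- c(sample(pos, length(pos), replace = TRUE),
                sample(neg, length(neg), replace = TRUE))
        bl <- rep(c(TRUE, FALSE), c(length(pos), length(neg)))
        auc_mann_whitney(bs, bl)
      }, numeric(1))
    })
    a <- (1 - level) / 2
    ci <- unname(quantile(boots, c(a, 1 - a), type = 7))
  }
  pmin(pmax(ci, 0), 1)
}

#' Empirical ROC curve
#'
#' Evaluates (sensitivity, specificity) at every distinct observed score
#' plus sentinels below the minimum (everyone test-positive) and above the
#' maximum (no one test-positive), and attaches the Mann-Whitney AUC with
#' its confidence interval. Sensitivity is non-increasing and specificity
#' non-decreasing in the cutoff.
#'
#' @inheritParams auc_ci
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @return object of class `fli_roc`: list with `points` (tibble: cutoff,
#'   se, sp), `auc`, `auc_ci`, `ci_method`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                      level = 0.95, n_boot = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  check_scores_labels(scores, labels)
  cuts <- sort(unique(scores))
  step <- if (length(cuts) > 1) min(diff(cuts)) else 1
  cuts <- c(cuts[1] - step, cuts, cuts[length(cuts)] + step)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  se <- vapply(cuts, function(k) sum(scores >= k & labels) / n_pos, numeric(1))
  sp <- vapply(cuts, function(k) sum(scores < k & !labels) / n_neg, numeric(1))
  structure(list(
    points = tibble::tibble(cutoff = cuts, se = se, sp = sp),
    auc = auc_mann_whitney(scores, labels),
    auc_ci = auc_ci(scores, labels, method = ci_method, level = level,
                    n_boot = n_boot, seed = seed),
    ci_method = ci_method, n_pos = n_pos, n_neg = n_neg),
    class = "fli_roc")
}

#' @export
print.fli_roc <- function(x, ...) {
  cat(sprintf("ROC: %d positives / %d negatives, AUC %.3f (%.3f-%.3f, %s)\n",
              x$n_pos, x$n_neg, x$auc, x$auc_ci[1], x$auc_ci[2], x$ci_method))
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' Scans a cutoff grid, computes Youden's J = se + sp - 1 at each value and
#' returns the maximizer. Ties are broken toward the smallest cutoff (which
#' maximizes sensitivity among the tied cutoffs). The default `"integer"`
#' grid (0-100 step 1) matches how FLI cutoffs are reported clinically;
#' `"observed"` scans every distinct score for full generality.
#'
#' @inheritParams roc_curve
#' @param grid `"integer"` (0..100) or `"observed"` (distinct scores).
#' @param stratum label recorded in the result (e.g. "total", "male").
#' @param compute_ci attach an AUC confidence interval (default `TRUE`;
#'   turning it off skips the CI computation in tight simulation loops).
#' @return object of class `cutoff_result`: list with `optimal_cutoff`,
#'   `metrics` (one-row tibble from [metrics_from_counts()]), `roc`
#'   (`fli_roc` or `NULL`), `auc`, `stratum`, `grid`.
#' @export
optimal_cutoff_youden <- function(scores, labels,
                                  grid = c("integer", "observed"),
                                  stratum = "total",
                                  ci_method = c("delong", "bootstrap"),
                                  level = 0.95, n_boot = 2000, seed = 1L,
                                  compute_ci = TRUE) {
  grid <- match.arg(grid)
  ci_method <- match.arg(ci_method)
  check_scores_labels(scores, labels)
  cuts <- if (grid == "integer") 0:100 else sort(unique(scores))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  j <- vapply(cuts, function(k) {
    sum(scores >= k & labels) / n_pos + sum(scores < k & !labels) / n_neg - 1
  }, numeric(1))
  best <- cuts[which.max(j)]  # which.max returns the first (smallest) maximizer
  metrics <- metrics_from_counts(confusion_at_cutoff(scores, labels, best),
                                 cutoff = best)
  roc <- if (compute_ci) {
    roc_curve(scores, labels, ci_method = ci_method, level = level,
              n_boot = n_boot, seed = seed)
  } else NULL
  structure(list(optimal_cutoff = best, metrics = metrics, roc = roc,
                 auc = auc_mann_whitney(scores, labels),
                 stratum = stratum, grid = grid),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Youden-optimal cutoff (%s stratum, %s grid): %g\n  J = %.3f, se = %.1f%%, sp = %.1f%%, AUC = %.3f\n",
    x$stratum, x$grid, x$optimal_cutoff, m$youden_j, 100 * m$se, 100 * m$sp,
    x$auc))
  invisible(x)
}

#' Validate fixed cutoffs
#'
#' Evaluates the full metric set at each supplied cutoff (test-positive is
#' score >= cutoff). When `prevalence` is supplied, prevalence-adjusted
#' predictive values from [metrics_from_rates()] are reported alongside the
#' empirical ones (columns `ppv_adj`, `npv_adj`); with `prevalence` equal to
#' the sample prevalence the two coincide.
#'
#' @inheritParams confusion_at_cutoff
#' @param cutoffs numeric vector of cutoffs (default the conventional 30
#'   rule-out / 60 rule-in pair).
#' @param prevalence optional assumed prevalence for adjusted predictive
#'   values.
#' @return tibble, one row per cutoff.
#' @export
evaluate_fixed_cutoffs <- function(scores, labels, cutoffs = c(30, 60),
                                   prevalence = NULL) {
  check_scores_labels(scores, labels)
  rows <- lapply(cutoffs, function(k) {
    m <- metrics_from_counts(confusion_at_cutoff(scores, labels, k), cutoff = k)
    if (!is.null(prevalence)) {
      adj <- metrics_from_rates(m$se, m$sp, prevalence)
      m$ppv_adj <- adj$ppv
      m$npv_adj <- adj$npv
    }
    m
  })
  dplyr::bind_rows(rows)
}

#' Sex-stratified (or pooled) cutoff optimization on a cohort
#'
#' Orchestrates the full accuracy analysis on a cohort table: computes FLI
#' scores if absent, builds the chosen reference standard, and runs
#' [optimal_cutoff_youden()] on the total population and/or separately per
#' sex. A stratum whose labels collapse to a single class is skipped with a
#' warning rather than failing the whole analysis.
#'
#' @param cohort cohort tibble.
#' @param reference `"us"` or `"cap"` (see [build_reference_labels()]).
#' @param strata `"total"`, `"by_sex"`, or both (default both).
#' @inheritParams optimal_cutoff_youden
#' @param cap_threshold CAP steatosis threshold passed through.
#' @return named list of `cutoff_result` objects (`total`, `male`,
#'   `female` as requested and available).
#' @export
stratified_analysis <- function(cohort, reference = c("us", "cap"),
                                strata = c("total", "by_sex"),
                                grid = c("integer", "observed"),
                                ci_method = c("delong", "bootstrap"),
                                level = 0.95, n_boot = 2000, seed = 1L,
                                cap_threshold = 248, compute_ci = TRUE) {
  reference <- match.arg(reference)
  strata <- match.arg(strata, several.ok = TRUE)
  grid <- match.arg(grid)
  ci_method <- match.arg(ci_method)
  if (!"fli" %in% names(cohort)) cohort <- add_indices(cohort)
  ref <- build_reference_labels(cohort, reference, cap_threshold = cap_threshold)
  sub <- cohort[ref$index, , drop = FALSE]
  labels <- ref$labels
  usable <- !is.na(sub$fli)
  sub <- sub[usable, , drop = FALSE]
  labels <- labels[usable]
  results <- list()
  run_one <- function(idx, name) {
    if (!any(labels[idx]) || all(labels[idx])) {
      warning("stratum '", name, "' has a single label class; skipped",
              call. = FALSE)
      return(NULL)
    }
    optimal_cutoff_youden(sub$fli[idx], labels[idx], grid = grid,
                          stratum = name, ci_method = ci_method,
                          level = level, n_boot = n_boot, seed = seed,
                          compute_ci = compute_ci)
  }
  if ("total" %in% strata) {
    results$total <- run_one(seq_along(labels), "total")
  }
  if ("by_sex" %in% strata) {
    for (sx in c("male", "female")) {
      idx <- which(!is.na(sub$sex) & sub$sex == sx)
      if (length(idx) == 0L) {
        warning("stratum '", sx, "' is empty; skipped", call. = FALSE)
        next
      }
      results[[sx]] <- run_one(idx, sx)
    }
  }
  results[!vapply(results, is.null, logical(1))]
}
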