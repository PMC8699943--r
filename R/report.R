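#' Round half away from zero
#'
#' Report tables use conventional half-up rounding (76.15 -> 76.2), not the
#' banker's rounding of [round()]. Applied only at the reporting layer;
#' all internal computation stays at full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a cohort table to delimited text
#'
#' Emits the canonical schema as a tab-separated file that [read_cohort()]
#' reads back.
#'
#' @param cohort cohort tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Baseline descriptive table with group comparisons
#'
#' Summarizes the cohort per sex, comparing subjects with and without the
#' chosen steatosis reference: mean +/- SD for approximately symmetric
#' variables, median (Q1, Q3) for right-skewed ones (triglycerides, CAP),
#' and count (%) for binary flags. Two-group p-values use the pooled-
#' variance independent t-test for continuous variables (on the log scale
#' for the skewed ones) and the chi-square test for categorical ones.
#'
#' @param cohort cohort tibble (comorbidity flags are derived if absent).
#' @param reference `"us"` or `"cap"` — which steatosis definition splits
#'   the groups.
#' @return tibble: sex, variable, summary for each group, group sizes,
#'   p_value (`NA` where a group is too small to test).
#' @export
baseline_table <- function(cohort, reference = c("us", "cap")) {
  reference <- match.arg(reference)
  if (!all(c("hypertension", "diabetes") %in% names(cohort))) {
    cohort <- derive_comorbidities(cohort)
  }
  status <- if (reference == "us") {
    cohort$us_steatosis
  } else {
    classify_cap_steatosis(cohort$cap)
  }
  cont_normal <- c("age", "sbp", "dbp", "bmi", "wc", "ast", "alt", "ggt")
  cont_skewed <- c("tg", "cap")
  cat_vars <- c("diabetes", "hypertension")
  fmt_mean <- function(x) sprintf("%.1f ± %.1f",
                                  round_half_up(mean(x), 1),
                                  round_half_up(sd(x), 1))
  fmt_med <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.0f (%.0f, %.0f)", q[2], q[1], q[3])
  }
  fmt_cat <- function(x) sprintf("%d (%.1f)", sum(x, na.rm = TRUE),
                                 round_half_up(100 * mean(x, na.rm = TRUE), 1))
  rows <- list()
  for (sx in c("male", "female")) {
    in_sex <- !is.na(cohort$sex) & cohort$sex == sx & !is.na(status)
    g0 <- cohort[in_sex & !status, , drop = FALSE]
    g1 <- cohort[in_sex & status, , drop = FALSE]
    if (nrow(g0) + nrow(g1) == 0L) next
    test_cont <- function(v, log_scale = FALSE) {
      a <- g0[[v]][!is.na(g0[[v]])]
      b <- g1[[v]][!is.na(g1[[v]])]
      if (length(a) < 2 || length(b) < 2) return(NA_real_)
      if (log_scale) { a <- log(a[a > 0]); b <- log(b[b > 0]) }
      if (sd(c(a, b)) == 0) return(1)
      t.test(a, b, var.equal = TRUE)$p.value
    }
    test_cat <- function(v) {
      a <- g0[[v]]; b <- g1[[v]]
      tab <- rbind(c(sum(a, na.rm = TRUE), sum(!a, na.rm = TRUE)),
                   c(sum(b, na.rm = TRUE), sum(!b, na.rm = TRUE)))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
      suppressWarnings(chisq.test(tab)$p.value)
    }
    for (v in cont_normal) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sex = sx, variable = v,
        no_disease = fmt_mean(g0[[v]][!is.na(g0[[v]])]),
        disease = fmt_mean(g1[[v]][!is.na(g1[[v]])]),
        n_no = nrow(g0), n_yes = nrow(g1),
        p_value = test_cont(v))
    }
    for (v in cont_skewed) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sex = sx, variable = v,
        no_disease = fmt_med(g0[[v]][!is.na(g0[[v]])]),
        disease = fmt_med(g1[[v]][!is.na(g1[[v]])]),
        n_no = nrow(g0), n_yes = nrow(g1),
        p_value = test_cont(v, log_scale = TRUE))
    }
    for (v in cat_vars) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sex = sx, variable = v,
        no_disease = fmt_cat(g0[[v]]),
        disease = fmt_cat(g1[[v]]),
        n_no = nrow(g0), n_yes = nrow(g1),
        p_value = test_cat(v))
    }
  }
  dplyr::bind_rows(rows)
}

# Format a cutoff_result list as a report table (optimal-cutoff layout).
optimal_cutoff_table <- function(results) {
  rows <- lapply(results, function(r) {
    m <- r$metrics
    ci <- if (!is.null(r$roc)) r$roc$auc_ci else c(NA_real_, NA_real_)
    tibble::tibble(
      stratum = r$stratum, cutoff = r$optimal_cutoff,
      auc = round_half_up(r$auc, 2),
      auc_ci_low = round_half_up(ci[1], 2),
      auc_ci_high = round_half_up(ci[2], 2),
      youden_j = round_half_up(m$youden_j, 3),
      sensitivity_pct = round_half_up(100 * m$se, 1),
      specificity_pct = round_half_up(100 * m$sp, 1),
      ppv_pct = round_half_up(100 * m$ppv, 1),
      npv_pct = round_half_up(100 * m$npv, 1))
  })
  dplyr::bind_rows(rows)
}

# Format evaluate_fixed_cutoffs output in the fixed-cutoff report layout.
fixed_cutoff_table <- function(metrics, reference, auc, auc_ci) {
  tibble::tibble(
    reference = reference,
    cutoff = metrics$cutoff,
    sensitivity_pct = round_half_up(100 * metrics$se, 1),
    specificity_pct = round_half_up(100 * metrics$sp, 1),
    ppv_pct = round_half_up(100 * metrics$ppv, 1),
    npv_pct = round_half_up(100 * metrics$npv, 1),
    auc = round_half_up(auc, 2),
    auc_ci_low = round_half_up(auc_ci[1], 2),
    auc_ci_high = round_half_up(auc_ci[2], 2),
    plr = ifelse(metrics$plr_infinite, Inf, round_half_up(metrics$plr, 1)),
    nlr = round_half_up(metrics$nlr, 1))
}

#' Run the full validation pipeline
#'
#' Executes read (or simulate) -> exclude -> score -> label -> evaluate ->
#' stratify and writes the report bundle to `out_dir`:
#' `exclusion_log.json`, `baseline_table.tsv`, `fixed_cutoffs.tsv`
#' (fixed-cutoff validation, one block per reference), `optimal_cutoffs.tsv`
#' (Youden-optimal cutoffs per stratum), `roc_<reference>_<stratum>.tsv`
#' (ROC vertices as 1-sp, se for external plotting) and `manifest.json`
#' (seed, parameters, package version — enough to reproduce the run).
#'
#' @param input path to a cohort file, a cohort tibble, or `NULL` to
#'   simulate from `synthetic` config.
#' @param out_dir output directory (created if needed).
#' @param reference `"us"`, `"cap"` or `"both"`.
#' @param cutoffs fixed cutoffs to validate (default 30 and 60).
#' @param grid cutoff search grid for the Youden optimum.
#' @param ci_method AUC confidence-interval method.
#' @param n_boot bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed seed for simulation and bootstrap.
#' @param synthetic optional [synthetic_config()] used when `input` is
#'   `NULL` (its own seed is overridden by `seed`).
#' @return invisibly, a list with the in-memory results (`cohort`,
#'   `exclusion_log`, `baseline`, `fixed`, `optimal`, `artifacts`).
#' @export
run_pipeline <- function(input = NULL, out_dir,
                         reference = c("both", "us", "cap"),
                         cutoffs = c(30, 60),
                         grid = c("integer", "observed"),
                         ci_method = c("delong", "bootstrap"),
                         n_boot = 2000, seed = 1L, synthetic = NULL) {
  reference <- match.arg(reference)
  grid <- match.arg(grid)
  ci_method <- match.arg(ci_method)
  refs <- if (reference == "both") c("us", "cap") else reference
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (is.null(input)) {
    cfg <- if (is.null(synthetic)) synthetic_config(seed = seed) else synthetic
    cfg$seed <- as.integer(seed)
    generate_cohort(cfg)
  } else if (is.character(input)) {
    read_cohort(input)
  } else {
    input
  }
  excl <- apply_exclusions(cohort)
  scored <- add_indices(excl$cohort)
  scored <- derive_comorbidities(scored)

  artifacts <- character()
  p <- function(f) file.path(out_dir, f)
  exclusion_log_json(excl$log, p("exclusion_log.json"))
  artifacts <- c(artifacts, p("exclusion_log.json"))

  base_tab <- baseline_table(scored, reference = refs[1])
  readr::write_tsv(base_tab, p("baseline_table.tsv"), progress = FALSE)
  artifacts <- c(artifacts, p("baseline_table.tsv"))

  fixed_rows <- list()
  optimal_rows <- list()
  optimal_results <- list()
  for (rf in refs) {
    ref <- build_reference_labels(scored, rf)
    sc <- scored$fli[ref$index]
    lb <- ref$labels
    ok <- !is.na(sc)
    sc <- sc[ok]; lb <- lb[ok]
    fx <- evaluate_fixed_cutoffs(sc, lb, cutoffs = cutoffs,
                                 prevalence = mean(lb))
    fixed_rows[[rf]] <- fixed_cutoff_table(
      fx, rf, auc = NA_real_, auc_ci = c(NA_real_, NA_real_))
    # per-cutoff AUC is the single global AUC; attach it to every row
    global_auc <- auc_mann_whitney(sc, lb)
    global_ci <- auc_ci(sc, lb, method = ci_method, n_boot = n_boot,
                        seed = seed)
    fixed_rows[[rf]]$auc <- round_half_up(global_auc, 2)
    fixed_rows[[rf]]$auc_ci_low <- round_half_up(global_ci[1], 2)
    fixed_rows[[rf]]$auc_ci_high <- round_half_up(global_ci[2], 2)

    res <- stratified_analysis(scored, reference = rf, grid = grid,
                               ci_method = ci_method, n_boot = n_boot,
                               seed = seed)
    optimal_results[[rf]] <- res
    tab <- optimal_cutoff_table(res)
    tab$reference <- rf
    optimal_rows[[rf]] <- tab
    for (nm in names(res)) {
      pts <- res[[nm]]$roc$points
      roc_tab <- tibble::tibble(fpr = 1 - pts$sp, se = pts$se)
      f <- p(sprintf("roc_%s_%s.tsv", rf, nm))
      readr::write_tsv(roc_tab, f, progress = FALSE)
      artifacts <- c(artifacts, f)
    }
  }
  fixed_tab <- dplyr::bind_rows(fixed_rows)
  readr::write_tsv(fixed_tab, p("fixed_cutoffs.tsv"), progress = FALSE)
  optimal_tab <- dplyr::bind_rows(optimal_rows)
  readr::write_tsv(optimal_tab, p("optimal_cutoffs.tsv"), progress = FALSE)
  artifacts <- c(artifacts, p("fixed_cutoffs.tsv"), p("optimal_cutoffs.tsv"))

  manifest <- list(
    package = "fliscreen",
    version = as.character(utils::packageVersion("fliscreen")),
    seed = seed,
    input = if (is.character(input)) input else
      if (is.null(input)) "synthetic" else "in-memory",
    reference = refs, cutoffs = cutoffs, grid = grid,
    ci_method = ci_method, n_boot = n_boot,
    n_initial = excl$log$n_initial, n_final = excl$log$n_final)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  artifacts <- c(artifacts, p("manifest.json"))

  invisible(list(cohort = scored, exclusion_log = excl$log,
                 baseline = base_tab, fixed = fixed_tab,
                 optimal = optimal_tab, optimal_results = optimal_results,
                 artifacts = artifacts))
}
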