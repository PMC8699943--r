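#' Cohort column schema
#'
#' Canonical subject-level fields used throughout the pipeline. Quantitative
#' fields carry the units of routine checkup reports: age (years), bmi
#' (kg/m^2), wc (cm), sbp/dbp (mmHg), fasting_glucose/tg/creatinine (mg/dL),
#' ast/alt/ggt (IU/L), alcohol (g/day), cap (dB/m), lsm_median (kPa).
#'
#' @return named character vector: field name -> storage type
#'   (`"numeric"`, `"logical"`, `"character"`).
#' @export
cohort_schema <- function() {
  c(subject_id = "character",
    sex = "character",
    age = "numeric", bmi = "numeric", wc = "numeric",
    sbp = "numeric", dbp = "numeric",
    fasting_glucose = "numeric", tg = "numeric",
    ast = "numeric", alt = "numeric", ggt = "numeric",
    creatinine = "numeric", alcohol = "numeric",
    hbv_positive = "logical", hcv_positive = "logical",
    on_antihypertensives = "logical", on_glucose_lowering = "logical",
    us_steatosis = "logical",
    cap = "numeric", lsm_median = "numeric",
    lsm_iqr_over_median = "numeric", lsm_n_valid = "numeric")
}

# Fields that must be present (possibly NA) as columns for the pipeline.
mandatory_fields <- function() {
  c("subject_id", "sex", "bmi", "wc", "tg", "ggt", "alcohol",
    "hbv_positive", "hcv_positive")
}

#' Default required-field set for the "missing information" exclusion
#'
#' The analysis-critical fields: everything the FLI needs, sex (needed for
#' the sex-specific alcohol limit and stratification) and at least one
#' reference label. Configurable because studies differ in what they count
#' as "missing information".
#' @return character vector of field names.
#' @export
default_required_fields <- function() {
  c("sex", "bmi", "wc", "tg", "ggt", "us_steatosis")
}

parse_logical_col <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Read a subject-level cohort table
#'
#' Reads a delimited text file (comma or tab, sniffed from the header line)
#' with one header row and one row per subject, maps columns onto the
#' canonical schema, and coerces types. Unparseable or out-of-plausible-range
#' cells become `NA` and are tallied in a parse report attached as the
#' `"parse_report"` attribute (retrieve with [parse_report()]).
#'
#' Range screening: quantitative fields must be non-negative; CAP, when
#' present, must lie in the plausibility window \[100, 400\] dB/m (device
#' output range) — values outside it are rejected to `NA` and counted.
#'
#' @param path path to the delimited text file.
#' @param schema optional named character vector mapping canonical field
#'   names to column names in the file (default: identical names).
#' @return a tibble with the canonical columns, one row per data row;
#'   attribute `"parse_report"` is a tibble (field, n_bad) of cells that
#'   were set to missing.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("read_cohort: file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    return(structure(empty_cohort(),
                     parse_report = tibble::tibble(field = character(),
                                                   n_bad = integer())))
  }
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  types <- cohort_schema()
  colmap <- stats::setNames(names(types), names(types))
  if (!is.null(schema)) {
    stopifnot(is.character(schema), !is.null(names(schema)))
    colmap[names(schema)] <- schema
  }
  absent <- mandatory_fields()[!(colmap[mandatory_fields()] %in% names(raw))]
  if (length(absent)) {
    stop("read_cohort: mandatory column(s) missing from file: ",
         paste(colmap[absent], collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  out <- vector("list", length(types))
  names(out) <- names(types)
  report <- integer(length(types))
  names(report) <- names(types)
  for (field in names(types)) {
    src <- colmap[[field]]
    if (!src %in% names(raw)) {
      out[[field]] <- switch(types[[field]],
                             numeric = rep(NA_real_, n),
                             logical = rep(NA, n),
                             character = rep(NA_character_, n))
      next
    }
    col <- raw[[src]]
    if (types[[field]] == "character") {
      out[[field]] <- as.character(col)
    } else if (types[[field]] == "logical") {
      # blank cells are uncounted missing; any other unparseable token
      # (including an explicit "NA" marker) is tallied in the parse report
      was_data <- !is.na(col) & trimws(col) != ""
      val <- parse_logical_col(col)
      report[[field]] <- sum(was_data & is.na(val))
      out[[field]] <- val
    } else {
      was_data <- !is.na(col) & trimws(col) != ""
      val <- suppressWarnings(as.numeric(col))
      val[is.nan(val)] <- NA_real_
      bad <- was_data & is.na(val)
      # plausibility screens: non-negative; CAP within the device window
      neg <- !is.na(val) & val < 0
      val[neg] <- NA_real_
      if (field == "cap") {
        oow <- !is.na(val) & (val < 100 | val > 400)
        val[oow] <- NA_real_
        bad <- bad | oow
      }
      report[[field]] <- sum(bad | neg)
      out[[field]] <- val
    }
  }
  if ("sex" %in% names(out)) {
    sx <- tolower(trimws(out$sex))
    sx[!sx %in% c("male", "female")] <- NA_character_
    report[["sex"]] <- report[["sex"]] + sum(!is.na(out$sex) & is.na(sx))
    out$sex <- sx
  }
  cohort <- tibble::as_tibble(out)
  attr(cohort, "parse_report") <-
    tibble::tibble(field = names(report),
                   n_bad = unname(report))[report > 0, , drop = FALSE]
  cohort
}

empty_cohort <- function() {
  types <- cohort_schema()
  out <- lapply(types, function(t) switch(t, numeric = numeric(),
                                          logical = logical(),
                                          character = character()))
  tibble::as_tibble(out)
}

#' Retrieve the parse report attached by [read_cohort()]
#' @param cohort a cohort tibble returned by [read_cohort()].
#' @return tibble with columns `field`, `n_bad`.
#' @export
parse_report <- function(cohort) {
  rep <- attr(cohort, "parse_report")
  if (is.null(rep)) tibble::tibble(field = character(), n_bad = integer()) else rep
}

#' Apply the study exclusion cascade
#'
#' Excludes subjects with potential non-NAFLD causes of liver disease or
#' unusable records, in the fixed order HBV-positive, then HCV-positive,
#' then significant alcohol intake (strictly above the sex-specific limit),
#' then missing required fields. Each subject is attributed to the first
#' matching reason only, so the per-reason counts are disjoint and sum to
#' the number excluded.
#'
#' @param cohort cohort tibble.
#' @param male_alcohol_max maximum acceptable intake for males, g/day
#'   (default 20; intake exactly at the limit is retained).
#' @param female_alcohol_max maximum for females, g/day (default 10).
#' @param required_fields fields whose absence triggers the "missing"
#'   exclusion (default [default_required_fields()]).
#' @return list with elements `cohort` (the retained rows) and `log`, an
#'   `exclusion_log` object with per-reason counts and n_initial/n_final.
#' @export
apply_exclusions <- function(cohort,
                             male_alcohol_max = 20,
                             female_alcohol_max = 10,
                             required_fields = default_required_fields()) {
  stopifnot(is.data.frame(cohort),
            male_alcohol_max > 0, female_alcohol_max > 0)
  n0 <- nrow(cohort)
  isTRUEv <- function(x) !is.na(x) & x
  hbv <- isTRUEv(cohort$hbv_positive)
  hcv <- !hbv & isTRUEv(cohort$hcv_positive)
  limit <- ifelse(!is.na(cohort$sex) & cohort$sex == "female",
                  female_alcohol_max, male_alcohol_max)
  alc <- !hbv & !hcv & !is.na(cohort$sex) &
    !is.na(cohort$alcohol) & cohort$alcohol > limit
  present <- intersect(required_fields, names(cohort))
  if (length(present) == 0L) {
    miss_any <- rep(FALSE, n0)
  } else {
    miss_any <- !complete.cases(cohort[present])
  }
  if (length(setdiff(required_fields, names(cohort)))) {
    miss_any <- rep(TRUE, n0)  # a wholly absent required column voids every row
  }
  mis <- !hbv & !hcv & !alc & miss_any
  keep <- !(hbv | hcv | alc | mis)
  log <- structure(
    list(reasons = tibble::tibble(
      reason = c("hbv", "hcv", "alcohol", "missing"),
      count = c(sum(hbv), sum(hcv), sum(alc), sum(mis))),
      n_initial = n0,
      n_final = sum(keep)),
    class = "exclusion_log")
  list(cohort = cohort[keep, , drop = FALSE], log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Exclusion cascade:", x$n_initial, "enrolled\n")
  for (i in seq_len(nrow(x$reasons))) {
    cat(sprintf("  - %-8s %d excluded\n",
                x$reasons$reason[i], x$reasons$count[i]))
  }
  cat(" ", x$n_final, "retained\n")
  invisible(x)
}

#' @export
format.exclusion_log <- function(x, ...) {
  paste0(x$n_initial, " - ",
         paste(x$reasons$count, collapse = " - "),
         " = ", x$n_final)
}

#' Serialize an exclusion log as JSON
#' @param log an `exclusion_log`.
#' @param path optional file to write to.
#' @return JSON string (invisibly if `path` given).
#' @export
exclusion_log_json <- function(log, path = NULL) {
  stopifnot(inherits(log, "exclusion_log"))
  obj <- list(n_initial = log$n_initial,
              excluded = stats::setNames(as.list(log$reasons$count),
                                         log$reasons$reason),
              n_final = log$n_final)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Derive comorbidity flags
#'
#' Hypertension: systolic pressure >= 140 mmHg, diastolic >= 90 mmHg, or
#' current antihypertensive medication. Diabetes: fasting glucose >= 126
#' mg/dL or glucose-lowering treatment. Missing inputs propagate as missing
#' flags unless another criterion already decides the flag (e.g. a treated
#' subject with unmeasured blood pressure is hypertensive).
#'
#' @param cohort cohort tibble.
#' @return the cohort with logical columns `hypertension` and `diabetes`
#'   appended.
#' @export
derive_comorbidities <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  cohort$hypertension <- (cohort$sbp >= 140) | (cohort$dbp >= 90) |
    cohort$on_antihypertensives
  cohort$diabetes <- (cohort$fasting_glucose >= 126) | cohort$on_glucose_lowering
  cohort
}
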