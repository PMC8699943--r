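# Shared fixture builders. All fixtures are constructed in code so tests
# carry no data files.

# A small fully-populated cohort tibble (n rows, deterministic content).
make_cohort_fixture <- function(n = 10, seed = 101) {
  withr::with_seed(seed, {
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      sex = sample(c("male", "female"), n, replace = TRUE),
      age = round(runif(n, 30, 75), 1),
      bmi = round(runif(n, 18, 32), 1),
      wc = round(runif(n, 65, 110), 1),
      sbp = round(runif(n, 100, 160)),
      dbp = round(runif(n, 60, 100)),
      fasting_glucose = round(runif(n, 80, 140)),
      tg = round(runif(n, 50, 250)),
      ast = round(runif(n, 15, 60)),
      alt = round(runif(n, 10, 70)),
      ggt = round(runif(n, 10, 120)),
      creatinine = round(runif(n, 0.6, 1.3), 2),
      alcohol = round(runif(n, 0, 30), 1),
      hbv_positive = sample(c(TRUE, FALSE), n, TRUE, prob = c(.1, .9)),
      hcv_positive = sample(c(TRUE, FALSE), n, TRUE, prob = c(.1, .9)),
      on_antihypertensives = sample(c(TRUE, FALSE), n, TRUE, prob = c(.2, .8)),
      on_glucose_lowering = sample(c(TRUE, FALSE), n, TRUE, prob = c(.1, .9)),
      us_steatosis = sample(c(TRUE, FALSE), n, TRUE),
      cap = round(runif(n, 150, 350)),
      lsm_median = round(runif(n, 3, 9), 1),
      lsm_iqr_over_median = round(runif(n, 0.05, 0.4), 2),
      lsm_n_valid = sample(8:12, n, TRUE))
  })
}

# Write a cohort tibble as a TSV file and return the path.
write_fixture_tsv <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                               .local_envir = parent.frame())) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# Random scores/labels with both classes guaranteed.
make_scores_labels <- function(n = 50, seed = 1, auc_shift = 1) {
  withr::with_seed(seed, {
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- rnorm(n) + auc_shift * labels
    list(scores = scores, labels = labels)
  })
}

# Independent brute-force AUC oracle: double loop over all
# positive x negative pairs, ties counted one half.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (x in pos) {
    for (y in neg) {
      total <- total + (x > y) + 0.5 * (x == y)
    }
  }
  total / (length(pos) * length(neg))
}
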