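test_that("confusion counts match a brute-force per-subject tally", {
  expect_equal(
    unclass(confusion_at_cutoff(c(10, 20, 30, 40), c(FALSE, FALSE, TRUE, TRUE), 30)),
    list(tp = 2L, fp = 0L, tn = 2L, fn = 0L), ignore_attr = TRUE)
  # cutoff 0: everyone test-positive
  c0 <- confusion_at_cutoff(c(10, 20, 30, 40), c(FALSE, FALSE, TRUE, TRUE), 0)
  expect_equal(c0$fp, 2L)
  expect_equal(c0$fn, 0L)
  # 20-point random fixture vs an explicit per-subject loop
  f <- make_scores_labels(20, seed = 4)
  for (k in c(-1, 0.2, 1.5)) {
    tp <- fp <- tn <- fn <- 0L
    for (i in 1:20) {
      pos <- f$scores[i] >= k
      if (pos && f$labels[i]) tp <- tp + 1L
      if (pos && !f$labels[i]) fp <- fp + 1L
      if (!pos && !f$labels[i]) tn <- tn + 1L
      if (!pos && f$labels[i]) fn <- fn + 1L
    }
    got <- confusion_at_cutoff(f$scores, f$labels, k)
    expect_equal(unclass(got), list(tp = tp, fp = fp, tn = tn, fn = fn),
                 ignore_attr = TRUE)
  }
  expect_error(confusion_at_cutoff(1:4, rep(TRUE, 4), 2), "degenerate")
})

test_that("metrics from counts reproduce hand arithmetic and edge contracts", {
  # chance performance
  m <- metrics_from_counts(list(tp = 25, fn = 25, tn = 25, fp = 25))
  expect_equal(c(m$se, m$sp, m$ppv, m$npv), rep(0.5, 4))
  expect_equal(c(m$plr, m$nlr), c(1, 1))
  expect_equal(m$youden_j, 0)
  # perfect classifier
  m <- metrics_from_counts(list(tp = 50, fn = 0, tn = 50, fp = 0))
  expect_equal(c(m$se, m$sp, m$youden_j), c(1, 1, 1))
  expect_equal(m$nlr, 0)
  expect_true(is.infinite(m$plr) && m$plr_infinite)
  # hand-computed ratios
  m <- metrics_from_counts(list(tp = 30, fn = 10, tn = 40, fp = 20))
  expect_equal(m$se, 30 / 40)
  expect_equal(m$sp, 40 / 60)
  expect_equal(m$ppv, 30 / 50)
  expect_equal(m$npv, 40 / 50)
  expect_equal(m$plr, (30 / 40) / (1 - 40 / 60))
  expect_equal(m$nlr, (1 - 30 / 40) / (40 / 60))
  expect_equal(m$youden_j, m$se + m$sp - 1)
  expect_error(metrics_from_counts(list(tp = 0, fn = 0, tn = 5, fp = 5)),
               "degenerate")
})

test_that("rate-based metrics apply Bayes' rule for predictive values", {
  m <- metrics_from_rates(1, 1, 0.3)
  expect_equal(c(m$ppv, m$npv, m$youden_j), c(1, 1, 1))
  # prevalence = sample prevalence reproduces empirical PPV/NPV exactly
  cm <- metrics_from_counts(list(tp = 30, fn = 10, tn = 40, fp = 20))
  prev <- (30 + 10) / 100
  adj <- metrics_from_rates(cm$se, cm$sp, prev)
  expect_equal(adj$ppv, cm$ppv)
  expect_equal(adj$npv, cm$npv)
  expect_true(metrics_from_rates(0.5, 1, 0.5)$plr_infinite)
  expect_true(is.na(metrics_from_rates(0.5, 0, 0.5)$nlr))
})

test_that("Mann-Whitney AUC equals the pairwise brute-force oracle", {
  expect_equal(auc_mann_whitney(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_mann_whitney(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc_mann_whitney(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  for (seed in 1:10) {
    n <- withr::with_seed(seed, sample(10:200, 1))
    f <- make_scores_labels(n, seed = seed, auc_shift = 0.5 * (seed %% 4))
    # include ties by coarse rounding on some instances
    if (seed %% 2 == 0) f$scores <- round(f$scores, 1)
    expect_equal(auc_mann_whitney(f$scores, f$labels),
                 brute_force_auc(f$scores, f$labels))
  }
})

test_that("label inversion maps AUC to its complement and swaps se/sp", {
  f <- make_scores_labels(120, seed = 13)
  expect_equal(auc_mann_whitney(f$scores, !f$labels),
               1 - auc_mann_whitney(f$scores, f$labels))
  m1 <- metrics_from_counts(confusion_at_cutoff(f$scores, f$labels, 0.5))
  # inverting labels AND the test direction swaps the roles of se and sp;
  # strictly-below cutoff equals the complement of the >= rule
  inv <- confusion_at_cutoff(-f$scores, !f$labels, -0.5 + 1e-12)
  m2 <- metrics_from_counts(inv)
  expect_equal(m2$se, m1$sp)
  expect_equal(m2$sp, m1$se)
})

test_that("DeLong interval agrees with the reference implementation", {
  f <- make_scores_labels(150, seed = 21)
  got <- auc_ci(f$scores, f$labels, method = "delong")
  ref <- suppressMessages(pROC::ci.auc(
    pROC::roc(response = f$labels, predictor = f$scores,
              direction = "<", quiet = TRUE), method = "delong"))
  expect_equal(got[1], as.numeric(ref[1]), tolerance = 1e-8)
  expect_equal(got[2], as.numeric(ref[3]), tolerance = 1e-8)
})

test_that("bootstrap interval is seed-deterministic and DeLong-consistent", {
  f <- make_scores_labels(200, seed = 31)
  b1 <- auc_ci(f$scores, f$labels, method = "bootstrap", n_boot = 500, seed = 5)
  b2 <- auc_ci(f$scores, f$labels, method = "bootstrap", n_boot = 500, seed = 5)
  expect_identical(b1, b2)
  d <- auc_ci(f$scores, f$labels, method = "delong")
  auc <- auc_mann_whitney(f$scores, f$labels)
  # both contain the point estimate and overlap each other
  expect_true(b1[1] <= auc && auc <= b1[2])
  expect_true(d[1] <= auc && auc <= d[2])
  expect_true(b1[1] <= d[2] && d[1] <= b1[2])
})

test_that("ROC staircase matches hand construction on a 4-point toy", {
  scores <- c(1, 2, 3, 4)
  labels <- c(FALSE, TRUE, FALSE, TRUE)
  r <- roc_curve(scores, labels)
  # hand-derived vertices at cutoffs 0,1,2,3,4,5
  expect_equal(r$points$cutoff, 0:5)
  expect_equal(r$points$se, c(1, 1, 1, 0.5, 0.5, 0))
  expect_equal(r$points$sp, c(0, 0, 0.5, 0.5, 1, 1))
  expect_equal(r$auc, 0.75)
  # monotone in the cutoff, and sentinels cover (1,0) and (0,1)
  expect_true(all(diff(r$points$se) <= 0))
  expect_true(all(diff(r$points$sp) >= 0))
})

test_that("duplicating a subject preserves ROC shape properties", {
  f <- make_scores_labels(40, seed = 8)
  r <- roc_curve(c(f$scores, f$scores[1]), c(f$labels, f$labels[1]))
  expect_true(all(diff(r$points$se) <= 0))
  expect_true(all(diff(r$points$sp) >= 0))
})

test_that("Youden optimizer equals an exhaustive grid scan", {
  # tie-break: perfectly separated toy, smallest integer cutoff with J = 1
  scores <- c(10, 20, 80, 90)
  labels <- c(FALSE, FALSE, TRUE, TRUE)
  res <- optimal_cutoff_youden(scores, labels, grid = "integer",
                               compute_ci = FALSE)
  expect_equal(res$optimal_cutoff, 21)
  expect_equal(res$metrics$youden_j, 1)
  # random fixtures vs an independent exhaustive scan over the grid
  for (seed in c(2, 3, 4)) {
    f <- make_scores_labels(50, seed = seed)
    f$scores <- 50 + 15 * f$scores  # put scores on the 0-100 scale
    for (g in c("integer", "observed")) {
      res <- optimal_cutoff_youden(f$scores, f$labels, grid = g,
                                   compute_ci = FALSE)
      cuts <- if (g == "integer") 0:100 else sort(unique(f$scores))
      js <- vapply(cuts, function(k) {
        m <- metrics_from_counts(confusion_at_cutoff(f$scores, f$labels, k))
        m$youden_j
      }, numeric(1))
      expect_equal(res$optimal_cutoff, cuts[which.max(js)])
      expect_equal(res$metrics$youden_j, max(js))
      # post-hoc: J at the optimum dominates every grid value
      expect_true(all(res$metrics$youden_j >= js))
    }
  }
})

test_that("AUC and ROC shape are invariant to monotone score transforms", {
  f <- make_scores_labels(80, seed = 17)
  f$scores <- 50 + 10 * f$scores
  trans <- function(x) exp(x / 20)  # strictly increasing
  expect_equal(auc_mann_whitney(trans(f$scores), f$labels),
               auc_mann_whitney(f$scores, f$labels))
  r1 <- roc_curve(f$scores, f$labels)
  r2 <- roc_curve(trans(f$scores), f$labels)
  expect_equal(r2$points[c("se", "sp")], r1$points[c("se", "sp")])
  # optimal observed-grid cutoff maps through the transform
  o1 <- optimal_cutoff_youden(f$scores, f$labels, grid = "observed",
                              compute_ci = FALSE)
  o2 <- optimal_cutoff_youden(trans(f$scores), f$labels, grid = "observed",
                              compute_ci = FALSE)
  expect_equal(o2$optimal_cutoff, trans(o1$optimal_cutoff))
})

test_that("fixed-cutoff validation composes counts, rates and Bayes", {
  # no score reaches the rule-in cutoff
  f <- list(scores = c(10, 20, 30, 40), labels = c(FALSE, TRUE, FALSE, TRUE))
  tab <- evaluate_fixed_cutoffs(f$scores, f$labels, cutoffs = 60)
  expect_equal(tab$se, 0)
  expect_equal(tab$sp, 1)
  expect_true(tab$plr_infinite)
  # 40-subject fixture: each row equals the compositional oracle
  f <- make_scores_labels(40, seed = 23)
  f$scores <- 50 + 15 * f$scores
  prev <- mean(f$labels)
  tab <- evaluate_fixed_cutoffs(f$scores, f$labels, cutoffs = c(30, 60),
                                prevalence = prev)
  for (i in 1:2) {
    oracle <- metrics_from_counts(
      confusion_at_cutoff(f$scores, f$labels, tab$cutoff[i]),
      cutoff = tab$cutoff[i])
    expect_equal(tab[i, names(oracle)], oracle)
    # Bayes self-consistency at the sample prevalence
    expect_equal(tab$ppv_adj[i], tab$ppv[i])
    expect_equal(tab$npv_adj[i], tab$npv[i])
  }
})

test_that("stratified analysis is consistent with pooled optimization", {
  coh <- generate_cohort(synthetic_config(n_total = 600, seed = 12))
  coh <- add_indices(coh)
  res <- stratified_analysis(coh, reference = "us", compute_ci = FALSE)
  pooled <- optimal_cutoff_youden(coh$fli, coh$us_steatosis,
                                  compute_ci = FALSE)
  expect_equal(res$total$optimal_cutoff, pooled$optimal_cutoff)
  expect_equal(res$total$metrics, pooled$metrics)
  expect_setequal(names(res), c("total", "male", "female"))
  # single-sex cohort: the missing stratum is skipped with a warning
  males <- coh[coh$sex == "male", ]
  expect_warning(res_m <- stratified_analysis(males, reference = "us",
                                              compute_ci = FALSE),
                 "female")
  expect_setequal(names(res_m), c("total", "male"))
})
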