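---
title: "Validating the fatty liver index: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the fatty liver index: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fliscreen)
```

## The problem

Nonalcoholic fatty liver disease (NAFLD) is usually screened for with
abdominal ultrasound, but ultrasound is absent from most mass health-checkup
programs. The fatty liver index (FLI) is a logistic score built from four
routinely collected quantities — serum triglycerides (TG, mg/dL), body mass
index (BMI, kg/m²), gamma glutamyl transpeptidase (GGT, IU/L) and waist
circumference (WC, cm):

$$\mathrm{FLI} = 100\cdot\sigma\!\left(0.953\ln TG + 0.139\,BMI +
0.718\ln GGT + 0.053\,WC - 15.745\right)$$

with $\sigma$ the standard logistic function, so the score lives strictly
inside (0, 100) and is strictly increasing in each input. The conventional
Western decision rules — FLI < 30 rules steatosis out, FLI ≥ 60 rules it in —
transfer poorly to Asian populations, whose central-obesity thresholds are
lower. `fliscreen` implements the full validation pipeline needed to re-derive
population-specific cutoffs: cohort exclusions, index computation, reference
standards, ROC analysis and Youden-index cutoff optimization, overall and by
sex.

## Cohort model and exclusions

Subjects enter as one row per person in a delimited text table
(`read_cohort()`), with unparseable or implausible cells (negative
quantities, CAP outside the 100–400 dB/m device range) demoted to missing
and tallied. The exclusion cascade (`apply_exclusions()`) removes, in fixed
order: hepatitis-B carriers, hepatitis-C carriers, subjects with significant
alcohol intake (strictly above 20 g/day for males, 10 g/day for females —
intake exactly at the limit is retained), and subjects missing
analysis-critical fields. Each subject is attributed to the *first* matching
reason, so the per-reason counts are disjoint and
`n_final = n_initial − Σ counts` is an exact identity, checked on every run.
Which fields count as "analysis-critical" is configurable
(`default_required_fields()`): the default is the FLI inputs, sex, and the
ultrasound label, since those are what the downstream analysis consumes.

Comorbidity flags follow the usual clinical definitions (hypertension:
SBP ≥ 140 or DBP ≥ 90 mmHg or antihypertensive treatment; diabetes: fasting
glucose ≥ 126 mg/dL or glucose-lowering treatment) and are descriptive only,
as is the MDRD-estimated GFR. For the MDRD equation we use the
IDMS-traceable 4-variable form (175 multiplier) without the ethnicity
coefficient; the choice is inconsequential because eGFR feeds nothing
downstream.

## Reference standards

Two binary references are supported. The ultrasound label is consumed as
given — sonographic criteria are image-level and deliberately out of scope.
The CAP reference applies the threshold rule CAP ≥ 248 dB/m
(boundary-inclusive; the threshold is a parameter). Liver-stiffness
reliability (≥ 10 valid shots and IQR/median < 0.3, or median < 7.1 kPa,
both bounds strict) is always computed and reported, but by default does
not gate the CAP analysis — sessions with ten valid measurements are kept,
and a switch (`require_reliable_lsm`) enables gating for sensitivity
analyses.

## Diagnostic accuracy

The test-positive rule is `score ≥ cutoff` throughout (the FLI is a rule-in
index). From the confusion counts we compute sensitivity, specificity,
predictive values, likelihood ratios and Youden's $J = se + sp - 1$;
prevalence-adjusted predictive values use Bayes' rule so printed operating
points can be transported to other prevalences. Undefined ratios are never
silently capped: an infinite LR+ is carried as `Inf` plus an explicit flag,
and zero-denominator predictive values are `NA`.

The AUC is the Mann–Whitney estimator (ties counted ½), computed from
midranks, which equals the trapezoidal area under the empirical ROC curve.
Its confidence interval uses the DeLong placement-value variance by default
(deterministic, the standard for a single curve); a stratified percentile
bootstrap (resampling positives and negatives separately, seed-controlled)
is available because published reports often leave the CI method unstated,
and the two should bracket each other on any well-behaved sample.

The Youden-optimal cutoff is an exhaustive scan over a grid — by default the
integers 0–100, matching how FLI cutoffs are reported and used clinically;
an "observed scores" grid is available for generality. Ties in $J$ break
toward the *smallest* cutoff, which maximizes sensitivity among the tied
values — an explicit choice, since published analyses rarely state their
tie-break. `stratified_analysis()` runs the search on the pooled cohort and
separately per sex, skipping (with a warning) any stratum whose labels
collapse to a single class.

## The synthetic cohort generator

No subject-level data from the reference validation study are available, so
the package ships a generator (`generate_cohort()`) that emulates the
published stratum structure: four (sex × ultrasound-steatosis) cells, each
with its own marginals — normal for age, BMI, WC, blood pressures, AST and
ALT (truncated at physiologic floors by redraw: BMI ≥ 12, WC ≥ 40 cm);
log-normal for GGT, moment-matched from its mean ± SD
(`lognormal_from_mean_sd()`); log-normal for triglycerides and CAP, fitted
through their median and quartiles (`lognormal_from_median_iqr()`), since
those right-skewed variables are reported that way. CAP is winsorized to
the 100–400 dB/m device range, which leaves its median and quartiles exact
(the clamp sits beyond the 98th percentile) while keeping every record
inside the ingestion plausibility window.

The published source reports marginals only, so dependence is an explicit
knob: a Gaussian copula imposes pairwise correlation 0.3 among the FLI
inputs (BMI, WC, TG, GGT) and 0.2 between CAP and each FLI input,
conditional on stratum — values in the range typically seen among adiposity
and liver-enzyme measures in checkup data. The ultrasound label *is* the
latent stratum assignment (the generator's ground truth), while CAP-defined
steatosis arises implicitly when the drawn CAP crosses 248 dB/m; the two
references are therefore imperfectly concordant, as in real cohorts.
Default composition: n = 4009, 83.5 % male, per-sex ultrasound-steatosis
prevalence 2162/3349 (males) and 301/661 (females). Treatment indicators
behind the comorbidity flags are drawn so derived prevalences land near the
stratum targets once the blood-pressure and glucose criteria contribute;
they are approximate descriptives, not calibration targets. A single master
seed drives everything, with per-stratum substreams so one stratum's draws
are reproducible when another's size changes.

What the generator does *not* emulate: the full cross-correlation structure
(AST/ALT/GFR are drawn independently of the copula block), comorbidity–lab
dependence, measurement error in the reference standards, and any
within-subject longitudinal structure. Passing pipeline-recovery tests on
synthetic cohorts therefore demonstrates that the *machinery* recovers the
structure it is fed — not that the published cutoffs are externally valid.

```{r example}
coh <- generate_cohort(synthetic_config(seed = 42))
res <- stratified_analysis(coh, reference = "us", seed = 42)
res$total
res$male
res$female
```

With the default correlation knob the pooled ultrasound AUC lands in the
low 0.80s and the female Youden-optimal cutoff sits well below the male one
— the sex dimorphism the stratified analysis exists to expose. Exact
reported cutoffs are not recoverable because the true inter-variable
correlations are unpublished; the package's acceptance checks therefore
assert bands (pooled AUC within 0.70–0.92, female optimum below male in
≥ 90 % of seeds over 25 default cohorts) rather than point values.

## Numerical and reporting choices

* All scores and metrics are computed and stored at full double precision;
  percentages and likelihood ratios are rounded half-up to one decimal only
  in the report tables (`round_half_up()`), matching clinical print style.
* Group comparisons in the baseline table use the pooled-variance two-sample
  t-test (on the log scale for triglycerides and CAP) and the chi-square
  test; every comparison in this design is two-group, so no multi-group
  ANOVA path exists.
* Degenerate inputs fail loudly: single-class labels raise errors rather
  than returning vacuous metrics, and empty strata are skipped with
  warnings in the stratified driver.
* Test-suite and acceptance problem sizes (cohorts of 300–4009, 25–100
  seeds) were chosen so each property is checked at the study's own scale
  while the whole suite completes in well under a minute.

## Limitations

The pipeline validates an index against an imperfect reference; it does not
model ultrasound misclassification, steatosis severity grades, fibrosis
staging, or verification bias in who receives which exam. The bundled
parameters describe one asymptomatic East-Asian checkup population; cutoffs
derived from them should not be transported elsewhere without re-running
the optimization on local data.
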