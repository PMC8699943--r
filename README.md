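# fliscreen

Diagnostic-accuracy pipeline for validating the **fatty liver index (FLI)**
as a noninvasive screen for hepatic steatosis (NAFLD) in health-checkup
populations, and for deriving population- and sex-specific FLI cutoffs.

Ultrasound — the usual first-line steatosis exam — is missing from most mass
screening programs, so claims-data studies fall back on the FLI, a logistic
score over four routinely measured quantities:

```
FLI = 100 · σ( 0.953·ln TG + 0.139·BMI + 0.718·ln GGT + 0.053·WC − 15.745 )
```

with TG serum triglycerides (mg/dL), BMI (kg/m²), GGT gamma glutamyl
transpeptidase (IU/L), WC waist circumference (cm) and σ the standard
logistic. The classical Western decision rules (< 30 rules out, ≥ 60 rules
in) perform poorly in Asian populations; re-deriving cutoffs requires the
full validation pipeline this package implements:

* **Cohort model** — delimited-text ingestion with plausibility screening,
  the exclusion cascade (HBV → HCV → alcohol > 20/10 g/day (m/f) → missing
  data, first-match attribution with auditable arithmetic), comorbidity
  flags, MDRD eGFR.
* **Reference standards** — ultrasound steatosis label (consumed as given)
  or CAP ≥ 248 dB/m from transient elastography, with LSM reliability
  screening (≥ 10 valid shots; IQR/median < 0.3 or median < 7.1 kPa).
* **Diagnostic accuracy** — Se/Sp/PPV/NPV/LR±/Youden J at any cutoff,
  prevalence-adjusted predictive values via Bayes' rule, Mann–Whitney AUC
  with DeLong or stratified-bootstrap confidence intervals, Youden-index
  cutoff optimization on an integer or observed-score grid, pooled and
  sex-stratified.
* **Synthetic cohort generator** — sex- × disease-status-conditional
  marginals (normal, and log-normal fitted from median/IQR or mean/SD)
  joined by a Gaussian copula, reproducing the composition of a published
  asymptomatic Korean checkup cohort (n = 4009, 83.5 % male), so the whole
  pipeline is testable without subject-level study data.
* **Reporting** — baseline descriptive table with group-comparison p-values,
  fixed-cutoff and optimal-cutoff report tables, ROC vertex export, JSON
  run manifest; a thin CLI lives in `inst/cli/fliscreen.R`.

## Worked example

```r
library(fliscreen)

coh <- generate_cohort(synthetic_config(seed = 42))  # 4009 synthetic subjects
res <- stratified_analysis(coh, reference = "us", seed = 42)
res$total
#> Youden-optimal cutoff (total stratum, integer grid): 31
#>   J = 0.477, se = 69.4%, sp = 78.3%, AUC = 0.814
res$male
#> Youden-optimal cutoff (male stratum, integer grid): 34
#>   J = 0.453, se = 68.1%, sp = 77.1%, AUC = 0.801
res$female
#> Youden-optimal cutoff (female stratum, integer grid): 20
#>   J = 0.505, se = 63.8%, sp = 86.7%, AUC = 0.805
```

The pooled AUC in the low 0.80s says the FLI discriminates ultrasound-visible
steatosis well in this population; the female optimum sitting far below the
male one (20 vs 34 here) is the sex dimorphism that motivates stratified
cutoffs. Fixed-cutoff validation of the classical rules on the same cohort:

```r
coh <- add_indices(coh)
evaluate_fixed_cutoffs(coh$fli, coh$us_steatosis, cutoffs = c(30, 60),
                       prevalence = mean(coh$us_steatosis))
#>   cutoff    se    sp   ppv   npv  plr   nlr
#>       30 0.707 0.767 0.829 0.620 3.03 0.382
#>       60 0.329 0.958 0.926 0.471 7.80 0.700
```

— the ≥ 60 rule is specific (95.8 %) but misses two thirds of cases
(sensitivity 32.9 %), which is exactly why a lower, locally optimized cutoff
is needed. An end-to-end report bundle (exclusion log, baseline table,
cutoff tables, ROC vertices, manifest):

```r
run_pipeline(input = NULL, out_dir = "report", reference = "both", seed = 1)
```

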