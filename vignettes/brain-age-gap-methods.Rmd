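---
title: "Methods: proteomic brain age, the brain age gap, and its dementia associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic brain age, the brain age gap, and its dementia associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(brainclock)
```

## The model in outline

`brainclock` implements an organ-specific proteomic aging analysis. The
chain of ideas is:

1. **Brain-enriched proteins.** A plasma protein is "brain-enriched" when its
   gene is expressed markedly higher in brain than in any other tissue.
   `classify_tissue_enriched()` applies the Human-Protein-Atlas-style rule to
   a genes-by-tissues bulk expression matrix: enrichment requires
   `expr(brain) >= fold_threshold * max(expr(other tissues))` (default
   fold 4, inclusive) *and* `expr(brain) >= expression_floor` (default 1
   nTPM-like unit). The floor suppresses infinite or unstable ratios at
   near-zero expression; the published convention does not print the exact
   parameters, so both are arguments.

2. **A proteomic brain-age clock.** `fit_clock()` regresses chronological age
   on the brain-enriched protein panel with gradient-boosted trees under
   k-fold cross-fitting: each participant's predicted age comes from an
   ensemble that never saw them. Cross-fitting matters because the gap
   statistic below is a residual — in-sample predictions would shrink it
   optimistically and leak age information into downstream hazard models.
   `boruta_select()` refines the panel (shadow-feature all-relevant
   selection) and `shapley_importance()` ranks proteins by mean absolute
   Shapley attribution, computed out-of-fold.

3. **The brain age gap.** Predicted age is a biased estimator of age
   (regression to the mean, possible nonlinearity), so the raw difference
   `predicted - chronological` correlates strongly with age. `compute_gap()`
   removes this by local regression: predicted age is smoothed against
   chronological age (tricube-weighted local linear fit, span 2/3), the gap
   is `predicted - fitted population mean`, and the gap is z-standardized
   over the cohort. The result is essentially uncorrelated with age
   (`decorrelation_check()`, default threshold |r| <= 0.001).
   `classify_agers()` labels |z| > 2 (strict) as extreme agers and splits the
   non-extremes into four equal-size groups.

4. **Association battery.** `fit_cox()` estimates the dementia hazard ratio
   per SD of the gap (and extreme-vs-non-extreme contrasts) under four
   covariate tiers: M1 (age, sex), M2 (M1 + race, education, deprivation,
   BMI, lifestyle, comorbidity and air-pollution covariates), M3 (M2 + APOE
   e4 count), M4 (M2 + Alzheimer's PRS tertile). `rcs_nonlinearity()` tests
   departure from log-linearity with a 5-knot restricted cubic spline
   (knots at the 5th/27.5th/50th/72.5th/95th gap percentiles, curve
   referenced at z = 0); `schoenfeld_check()` tests proportional hazards;
   `fine_gray_fit()` re-estimates the association on the subdistribution
   hazard with death as a competing risk; `subgroup_interactions()` and
   `sensitivity_suite()` complete the battery.

5. **Neuroimaging.** `residualize_volumes()` regresses ten MRI volume
   phenotypes on image confounders (head size, four position covariates,
   imaging centre) and standardizes the residuals; white-matter
   hyperintensity is log-transformed first (natural log; strictly positive
   input required, no offset added). `volume_association()` then regresses
   these scaled residuals on the gap, adjusting for the M3 covariates plus
   scan interval, Parkinson's disease and multiple sclerosis.

## What the synthetic cohort emulates

All statistical guarantees in the test suite are established on
`simulate_cohort()` output. Its central device is a latent per-participant
aging offset `delta ~ N(0, sigma_delta^2)` that simultaneously drives

- the informative brain-enriched proteins (`a_j + b_j (age + delta) + noise`,
  slopes log-normal so importance rankings are non-degenerate),
- the dementia hazard (`lambda_0 exp(beta_age (age-55) + beta_sex male +
  beta_apoe e4 + theta delta/sigma_delta)` with exponential event times,
  administrative censoring at 15 years, and a competing death process at
  twice the dementia baseline hazard), and
- the volume phenotypes (linear in age and standardized delta, atrophy signs
  for gray matter/total brain/hippocampus, growth for white-matter
  hyperintensity and ventricular CSF; WMH log-normal).

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| ages | Uniform(40, 70) y | middle-aged recruitment window |
| `sigma_delta` | 3.26 y | spread of a refined proteomic brain age gap |
| true log-HR | log(1.67) per SD | the association strength the Cox stage must recover |
| baseline hazard | 0.00115 /py | yields ~1,300 dementia events at n = 40,000 over the 15 y horizon (≈ 1,289/45,374 at 13.75 y median follow-up) |
| death hazard | 2x dementia | deaths outnumber dementia events, so Fine-Gray has work to do |
| APOE e4 freqs | .708/.262/.030 | population allele-count distribution |
| protein missingness | MCAR 2% per protein | exercises the "over 10%" QC rule without triggering it |
| imaging fraction | 8% | imaging-subsample proportion (3,695 of ~46,000) |

The generator does **not** emulate: real Olink NPX distributions, plate or
limit-of-detection effects, genotype structure beyond the e4 count and a PRS
tertile label, dependence among lifestyle covariates (marginals are drawn
independently, which overstates independence relative to a real cohort), or
informative censoring. A passing suite therefore demonstrates that the
*machinery* is correct at realistic scales and effect sizes, not that any
particular biological result generalizes.

Proportional hazards deliberately holds in the default generator. A shared
Weibull shape (`weibull_shape`) rescales time but preserves proportionality,
so it cannot produce a PH violation; the violation fixture instead switches
the exposure's log-HR at a change point (`log_hr_late`, `hr_change_time`),
which the Schoenfeld test detects reliably.

## Numerical and design choices

- **LOESS is authored in-package** as the classic nearest-neighbour tricube
  local regression: `ceiling(span * n)` nearest points, weights
  `(1-(d/dmax)^3)^3`, weighted least squares of degree 1 (degree is an
  argument; no robustness iterations), evaluated on a 512-point grid with
  linear interpolation. The grid is dense enough that interpolation error is
  orders of magnitude below noise at cohort scale. Windows become asymmetric
  at the age-range edges; this boundary behaviour is the main residual
  source of gap-age correlation and is why the decorrelation check is a
  statistical, not exact, guarantee.
- **z-standardization before classification.** The gap z-score uses the full
  cohort including future extremes, and extremes are classified afterwards
  with strict inequalities; quartiles of the non-extremes are as equal as
  possible (sizes differ by at most one, lower quartiles take remainders,
  ties broken by participant id).
- **Gradient-boosting backend.** xgboost with histogram trees, depth <= 6,
  learning rate 0.05, up to 500 rounds with early stopping on an internal
  20% split of each training fold; single-threaded for bit-reproducibility.
  Because trees are stored in single precision, Shapley additivity holds to
  ~1e-5 relative (asserted at 1e-4 absolute), not machine precision.
- **Boruta decisions** use a two-sided binomial test of hit counts against
  Binomial(iterations, 1/2), Bonferroni-corrected across the original
  features; rejected features leave the design, undecided features stay
  "tentative". A caveat documented here on purpose: a population-independent
  feature whose *sample* correlation with age is unusually large is
  consistently confirmed — all-relevant selection operates on the sample,
  and its null false-confirm rate is a few percent per dataset rather than
  alpha/m. Tests budget accordingly.
- **Cox details.** Efron tie handling everywhere (synthetic times are
  continuous, user data may have ties). The restricted cubic spline uses
  Harrell's truncated-power basis normalized by the squared boundary span;
  5 knots give 4 columns and the nonlinearity test is a joint Wald test on
  the 3 nonlinear coefficients. The Schoenfeld trend test uses the
  Kaplan-Meier time transform by default ("rank"/"identity" by argument).
  Fine-Gray is fitted by expanding to weighted subdistribution risk sets
  (reverse Kaplan-Meier censoring weights, not covariate-adjusted) and
  maximizing the weighted partial likelihood; with no competing events it
  coincides with the cause-specific model to numerical precision. 95% CIs
  are the normal approximation `exp(beta +/- 1.96 se)`.
- **"Most conservative tier".** All four tiers are reported; in practice the
  tier with the smallest absolute log-HR (typically the APOE-adjusted M3) is
  the one to treat as primary.
- **Parameter-recovery experiments** use the generator's ground-truth
  standardized offset as the exposure — the gap a noiseless clock would
  produce. This isolates the survival stage: running the estimated clock
  first attenuates the log-HR by measurement error (a property of the
  measurement, not a defect of the Cox stage), which would conflate the two
  stages in a recovery test.
- **Imaging.** "Scaled residuals" means z-scored OLS residuals (mean 0,
  SD 1). Imaging centre enters as indicator columns (first centre
  lexicographically as reference). Residualization runs on the imaging
  subsample only.

## Validation at scale (problem sizes used)

The test suite establishes, among others:

- LOESS fitted values equal an independent per-point tricube WLS oracle to
  1e-6 on linear, quadratic and noisy fixtures (n = 200).
- Cox log-HRs equal brute-force partial-likelihood maximization to 1e-6 on
  finite-MLE toy datasets of 3-6 subjects.
- Detrending decorrelation: median |r(gap z, age)| <= 0.001 over 5 seeds at
  n = 45,000 with a nonlinearly biased predictor; skipping the detrending
  fails the same check by two orders of magnitude.
- Hazard-ratio recovery: across 50 replicates at n = 40,000 (~1,300 events,
  true HR 1.67/SD), the mean log-HR sits within 2 Monte-Carlo SEs of truth
  with 95% CI coverage in [90%, 99%].
- Null calibration of the Schoenfeld, spline-nonlinearity and interaction
  tests at the 5% level within 3 binomial SEs (200 replicates of n = 4,000;
  replicate size chosen to keep the full suite fast while leaving >100
  events per replicate).
- Boruta recovers >= 9/10 planted informative proteins and rejects >= 45/50
  noise proteins in >= 90% of 20 seeds at n = 3,000.
- The imaging stage recovers the planted volume sign pattern in >= 90% of 20
  seeds at the imaging-subsample size (n = 3,695 scans).

## Known limitations

- The enrichment rule covers only the single-tissue "enriched" category, not
  group-enriched or enhanced classes.
- Protein missingness handling (median imputation after the >10% exclusion)
  is an explicit assumption; upstream pipelines may differ.
- No left truncation, frailty, or time-varying covariates in the survival
  stage; event labels are inputs, not derived from health records.
- The LOESS degree (1) and absence of robustness weighting are choices;
  degree 2 is available by argument.
- Quartile groups feed the descriptive baseline table only; no regression is
  fitted on quartiles.
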