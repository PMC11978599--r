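# brainclock

Plasma proteomic brain-age clocks and brain-age-gap epidemiology in R.

Organ-specific aging asks a sharper question than whole-body aging: do the
plasma proteins that originate preferentially in one organ carry a signal
about how fast *that* organ is aging? `brainclock` implements this program
for the brain. It classifies **brain-enriched proteins** (genes expressed
markedly higher in brain than in any other tissue), trains a
gradient-boosted **proteomic age clock** on them, converts predictions into
the **brain age gap** — the LOESS-detrended, z-standardized difference
between predicted and chronological age — and runs the downstream
epidemiology: covariate-tiered Cox models for incident dementia, restricted
cubic-spline nonlinearity tests, Schoenfeld diagnostics, Fine–Gray
competing-risks models, subgroup interaction tests, and associations with
residualized brain MRI volumes.

The package is aimed at biostatisticians and epidemiologists who want a
tested, reusable implementation of this pipeline. Cohort-scale data of this
kind is access-controlled, so the package ships a first-class **synthetic
cohort generator** whose latent per-person aging offset `δ` simultaneously
drives protein levels, dementia hazard, and brain volumes; every stage is
validated against that known ground truth.

## The statistic at the core

For participant *i* with chronological age `a_i` and clock prediction
`p_i` (out-of-fold, so never fitted on participant *i*):

```
m(a)    = tricube-weighted local linear fit of p on a (span 2/3)
gap_i   = p_i − m(a_i)
z_i     = (gap_i − mean(gap)) / sd(gap)
```

Detrending against the fitted mean `m(a)` rather than `a` itself removes
the regression-to-the-mean bias of age clocks, leaving `z` essentially
uncorrelated with age (|r| ≤ 0.001 at cohort scale). Participants with
`z < −2` / `z > 2` (strict) are extreme young/old agers; the hazard model
estimates `HR = exp(θ)` per SD of gap from the Cox partial likelihood
under four covariate tiers (age+sex; +lifestyle/comorbidity; +APOE ε4;
+AD polygenic score).

## Worked example

```r
library(brainclock)

cfg   <- sim_config(n_participants = 4000, seed = 3)
expr  <- simulate_tissue_expression(cfg)
sim   <- simulate_cohort(cfg)

calls <- classify_tissue_enriched(expr, "brain")     # ≥4-fold over max other tissue
panel <- sim$proteins |>
  qc_filter_proteins() |> (\(x) x$proteins)() |>     # drop >10%-missing proteins
  impute_protein_values() |>
  select_brain_enriched(calls)

clock <- fit_clock(panel, sim$cohort$age, seed = 1)
glance(clock)
#>       n n_proteins n_folds r_squared pearson_r  rmse
#> 1  4000         10       5     0.816     0.903  3.73

gaps <- compute_gap(clock$predictions, age = "age") |> classify_agers()
decorrelation_check(gaps)
#>   pearson_r   abs_r threshold pass
#> 1   0.00645 0.00645     0.001 FALSE

analysis <- prepare_covariates(sim$cohort) |>
  dplyr::inner_join(tibble::as_tibble(gaps)[c("participant", "gap_z", "ager_class")],
                    by = "participant")
fit_cox(analysis, model_spec("M3", "all_cause", "gap_z"))
#>   term  estimate     se    hr conf.low conf.high  p_value tier outcome
#> 1 gap_z    0.492 0.0947  1.64     1.36      1.97  2.01e-7 M3   all_cause
```

Reading the output: the clock explains 82% of age variance with an
out-of-fold RMSE of 3.7 years; the fully adjusted (APOE-tier) hazard ratio
1.64 per SD of gap brackets the generator's true value 1.67. The
decorrelation check *fails* here by design — its 0.001 threshold is a
cohort-scale criterion, and at n = 4,000 the sampling noise of a
correlation is an order of magnitude larger; at n = 45,000 the same
pipeline passes (see below).

`run_pipeline()` executes the whole chain (simulate → enrich/QC → clock →
gap → survival battery → imaging → report) from one YAML or list config and
writes tidy CSVs, a Markdown report, and a checksum manifest.

## Documentation

The methods vignette (`vignettes/brain-age-gap-methods.Rmd`) describes the
model, the generator's design and its deliberate limitations, every tunable
parameter with its default and rationale, and the validation suite's
problem sizes.
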