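# One larger cohort shared across the distributional checks below.
big_cfg <- sim_config(n_participants = 20000L, seed = 11L)
big_sim <- simulate_cohort(big_cfg)

test_that("generator is bit-reproducible given config and seed", {
  cfg <- sim_config(n_participants = 300L, seed = 7L)
  expect_identical(simulate_tissue_expression(cfg),
                   simulate_tissue_expression(cfg))
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_neuroimaging(s1$cohort, s1$truth, cfg),
                   simulate_neuroimaging(s2$cohort, s2$truth, cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(age_range = c(70, 40)), "age_range")
  expect_error(sim_config(n_brain_enriched = 80, n_proteins = 60),
               "n_informative <= n_brain_enriched <= n_proteins")
  expect_error(sim_config(n_informative = 20, n_brain_enriched = 10),
               "n_informative")
  expect_error(sim_config(apoe_freqs = c(0.5, 0.4, 0.2)), "apoe_freqs")
  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
  expect_error(sim_config(imaging_fraction = 0), "imaging_fraction")
  expect_error(sim_config(log_hr_late = 0, weibull_shape = 1.5),
               "weibull_shape")
})

test_that("tissue matrix plants exactly the configured number of enriched genes", {
  for (k in c(0L, 3L, 10L)) {
    cfg <- sim_config(n_participants = 50L, n_proteins = 12L,
                      n_brain_enriched = k, n_informative = k, seed = 5L)
    expr <- simulate_tissue_expression(cfg)
    calls <- classify_tissue_enriched(expr, "brain")
    expect_identical(sum(calls$enriched), as.integer(k))
    expect_setequal(calls$gene[calls$enriched], attr(expr, "brain_enriched"))
    expect_true(all(as.matrix(expr[setdiff(names(expr), "gene")]) >= 0))
  }
})

test_that("categorical covariate marginals are calibrated at large n", {
  co <- big_sim$cohort
  n <- nrow(co)
  apoe_hat <- as.numeric(table(factor(co$apoe_e4_count, levels = 0:2))) / n
  for (k in 1:3) {
    p <- big_cfg$apoe_freqs[k]
    expect_lt(abs(apoe_hat[k] - p), 3 * sqrt(p * (1 - p) / n))
  }
  for (v in c("sex_male", "hypertension", "depression")) {
    p <- brainclock:::default_covariate_freqs()[[v]]
    expect_lt(abs(mean(co[[v]]) - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_true(all(co$time > 0))
  expect_true(all(co$event_type %in% c("censored", "dementia", "death")))
  # subtype flags imply the all-cause flag
  expect_true(all(co$event_all_cause[co$event_ad == 1] == 1))
  expect_true(all(co$event_all_cause[co$event_vascular == 1] == 1))
})

test_that("latent offset behaves as configured", {
  co <- big_sim$truth$delta
  expect_lt(abs(mean(co$delta)),
            3 * big_cfg$sigma_delta / sqrt(nrow(co)))
  expect_true(all(big_sim$truth$informative_protein_ids %in%
                    big_sim$truth$brain_enriched_ids))

  cfg0 <- sim_config(n_participants = 200L, sigma_delta = 0, seed = 2L)
  s0 <- simulate_cohort(cfg0)
  expect_true(all(s0$truth$delta$delta == 0))
})

test_that("dementia incidence rises across deciles of the latent offset", {
  cfg <- sim_config(n_participants = 40000L, seed = 21L)
  sim <- simulate_cohort(cfg)
  dec <- dplyr::ntile(sim$truth$delta$delta, 10)
  rate <- tapply(sim$cohort$event_all_cause, dec, mean)
  expect_gt(cor(seq_len(10), rate, method = "spearman"), 0)
})

test_that("a null exposure effect leaves incidence flat across offset tertiles", {
  n_sig <- 0L
  n_seeds <- 25L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_participants = 4000L, log_hr_per_sd_gap = 0,
                      seed = 100L + s)
    sim <- simulate_cohort(cfg)
    ter <- dplyr::ntile(sim$truth$delta$delta, 3)
    p <- suppressWarnings(
      stats::chisq.test(table(ter, sim$cohort$event_all_cause))$p.value)
    if (p < 0.01) n_sig <- n_sig + 1L
  }
  # expect roughly 1% false positives; allow up to 3 of 25
  expect_lte(n_sig, 3L)
})

test_that("imaging volumes carry the planted signs and a skewed positive WMH", {
  cfg <- sim_config(n_participants = 40000L, seed = 31L)
  sim <- simulate_cohort(cfg)
  vols <- simulate_neuroimaging(sim$cohort, sim$truth, cfg)
  expect_equal(nrow(vols), round(cfg$imaging_fraction * 40000))
  dz <- sim$truth$delta$delta_z[match(vols$participant,
                                      sim$cohort$participant)]
  expect_lt(cor(dz, vols$gray_matter), 0)
  expect_lt(cor(dz, vols$total_brain), 0)
  expect_gt(cor(dz, log(vols$wmh)), 0)
  expect_gt(cor(dz, vols$ventricular_csf), 0)
  expect_true(all(vols$wmh > 0))
  expect_gt(skewness(vols$wmh), 0)
  phen <- brainclock:::volume_phenotypes()
  expect_true(all(as.matrix(vols[phen]) >= 0))
})

test_that("biased-clock predictions have the configured distortion", {
  d <- simulate_biased_predictions(n = 5000, seed = 4)
  expect_lt(cor(d$predicted_age - d$age, d$age), -0.3)
  d2 <- simulate_biased_predictions(n = 5000, seed = 4)
  expect_identical(d, d2)
})

test_that("simulation files round-trip through the plain-text writers", {
  cfg <- sim_config(n_participants = 60L, seed = 9L)
  sim <- simulate_cohort(cfg)
  expr <- simulate_tissue_expression(cfg)
  vols <- simulate_neuroimaging(sim$cohort, sim$truth, cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, expr, vols, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[["cohort"]], show_col_types = FALSE)
  expect_equal(nrow(back), 60L)
  expect_equal(back$age, sim$cohort$age, tolerance = 1e-12)
})
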