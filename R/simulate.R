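#' Simulation configuration for the synthetic brain-aging cohort
#'
#' Bundles every knob of the synthetic-data generator. The generator encodes a
#' latent per-participant brain-aging offset `delta` (years, mean zero) that
#' simultaneously drives a subset of brain-enriched plasma proteins, the
#' dementia hazard, and brain MRI volume phenotypes, so each downstream stage
#' of the pipeline can be validated against a known ground truth.
#'
#' Defaults emulate a UK-Biobank-like middle-aged cohort: recruitment ages
#' uniform on 40-70 years, an aging-offset SD of 3.26 years (the spread of a
#' refined proteomic brain age gap), a true hazard ratio of 1.67 per SD of the
#' offset, a dementia baseline hazard of 0.00115 events/person-year with a
#' competing death hazard twice that, administrative censoring at 15 years,
#' and APOE e4 allele-count frequencies (0.708, 0.262, 0.030).
#'
#' @param n_participants Cohort size.
#' @param age_range Recruitment window in years, `c(low, high)`.
#' @param n_proteins Total proteins assayed.
#' @param n_brain_enriched Number of proteins whose genes are brain-enriched.
#' @param n_informative Number of brain-enriched proteins that track
#'   `age + delta` (the rest of the brain-enriched panel tracks age only;
#'   non-brain proteins are pure noise).
#' @param sigma_delta SD (years) of the latent aging offset.
#' @param protein_noise_sd Residual SD of each protein on its NPX-like scale.
#' @param log_hr_per_sd_gap True log hazard ratio for dementia per SD of the
#'   aging offset.
#' @param baseline_hazard Dementia baseline hazard (events/person-year).
#' @param death_hazard Competing death baseline hazard; defaults to twice the
#'   dementia hazard.
#' @param death_log_hr_per_sd_gap Log-HR of death per SD of the offset.
#' @param censoring_horizon Administrative censoring time (years).
#' @param missing_rate Per-protein completely-at-random missingness rate.
#' @param covariate_missing_rate MCAR missingness rate applied to BMI,
#'   education and the Townsend index (exercises covariate imputation and the
#'   complete-case sensitivity analysis).
#' @param apoe_freqs Probabilities of carrying 0/1/2 APOE e4 alleles.
#' @param weibull_shape Shape of the Weibull baseline hazard (1 = exponential).
#'   A shared shape rescales time but preserves proportional hazards.
#' @param log_hr_late If non-`NULL`, the exposure log-HR switches from
#'   `log_hr_per_sd_gap` to this value at `hr_change_time`, producing a genuine
#'   proportional-hazards violation (requires `weibull_shape = 1`).
#' @param hr_change_time Change point (years) for `log_hr_late`.
#' @param age_log_hr,sex_log_hr,apoe_log_hr Log-HRs of dementia per year of
#'   age (centred at 55), for male sex, and per APOE e4 allele.
#' @param ad_fraction,vascular_fraction Fraction of dementia events labelled
#'   Alzheimer's disease / vascular dementia (independent thinning, so each
#'   subtype inherits the same true log-HR).
#' @param imaging_fraction Fraction of the cohort with MRI volumes.
#' @param seed Integer seed; all outputs are bit-reproducible given the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 10000L,
                       age_range = c(40, 70),
                       n_proteins = 60L,
                       n_brain_enriched = 10L,
                       n_informative = 10L,
                       sigma_delta = 3.26,
                       protein_noise_sd = 1,
                       log_hr_per_sd_gap = log(1.67),
                       baseline_hazard = 0.00115,
                       death_hazard = 2 * baseline_hazard,
                       death_log_hr_per_sd_gap = 0.1,
                       censoring_horizon = 15,
                       missing_rate = 0.02,
                       covariate_missing_rate = 0.03,
                       apoe_freqs = c(0.708, 0.262, 0.030),
                       weibull_shape = 1,
                       log_hr_late = NULL,
                       hr_change_time = 5,
                       age_log_hr = 0.09,
                       sex_log_hr = 0.15,
                       apoe_log_hr = 0.6,
                       ad_fraction = 0.446,
                       vascular_fraction = 0.168,
                       imaging_fraction = 0.08,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants), age_range = age_range,
    n_proteins = as.integer(n_proteins),
    n_brain_enriched = as.integer(n_brain_enriched),
    n_informative = as.integer(n_informative),
    sigma_delta = sigma_delta, protein_noise_sd = protein_noise_sd,
    log_hr_per_sd_gap = log_hr_per_sd_gap,
    baseline_hazard = baseline_hazard, death_hazard = death_hazard,
    death_log_hr_per_sd_gap = death_log_hr_per_sd_gap,
    censoring_horizon = censoring_horizon, missing_rate = missing_rate,
    covariate_missing_rate = covariate_missing_rate,
    apoe_freqs = apoe_freqs, weibull_shape = weibull_shape,
    log_hr_late = log_hr_late, hr_change_time = hr_change_time,
    age_log_hr = age_log_hr, sex_log_hr = sex_log_hr,
    apoe_log_hr = apoe_log_hr,
    ad_fraction = ad_fraction, vascular_fraction = vascular_fraction,
    imaging_fraction = imaging_fraction, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_number(cfg$n_participants, "n_participants", lower = 1)
  if (length(cfg$age_range) != 2L || cfg$age_range[1] >= cfg$age_range[2]) {
    abort("`age_range` must be c(low, high) with low < high")
  }
  if (cfg$n_informative > cfg$n_brain_enriched ||
      cfg$n_brain_enriched > cfg$n_proteins) {
    abort("need n_informative <= n_brain_enriched <= n_proteins")
  }
  assert_number(cfg$sigma_delta, "sigma_delta", lower = 0)
  assert_number(cfg$protein_noise_sd, "protein_noise_sd", lower = 0)
  assert_number(cfg$baseline_hazard, "baseline_hazard", lower = 0)
  assert_number(cfg$death_hazard, "death_hazard", lower = 0)
  assert_number(cfg$censoring_horizon, "censoring_horizon", lower = 0)
  assert_prob(cfg$missing_rate, "missing_rate")
  assert_prob(cfg$covariate_missing_rate, "covariate_missing_rate")
  if (length(cfg$apoe_freqs) != 3L || any(cfg$apoe_freqs < 0) ||
      abs(sum(cfg$apoe_freqs) - 1) > 1e-12) {
    abort("`apoe_freqs` must be 3 non-negative probabilities summing to 1")
  }
  assert_number(cfg$weibull_shape, "weibull_shape", lower = 1e-6)
  if (!is.null(cfg$log_hr_late) && cfg$weibull_shape != 1) {
    abort("piecewise exposure effect (`log_hr_late`) requires weibull_shape = 1")
  }
  if (cfg$imaging_fraction <= 0 || cfg$imaging_fraction > 1) {
    abort("`imaging_fraction` must be in (0, 1]")
  }
  invisible(cfg)
}

protein_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_proteins))

# Which genes are brain-enriched and which of those carry the latent offset.
# Drawn from a dedicated seed so the tissue matrix and the cohort agree.
brain_gene_roles <- function(cfg) {
  genes <- protein_ids(cfg)
  set.seed(cfg$seed + 303L)
  enriched <- sort(sample(genes, cfg$n_brain_enriched))
  informative <- sort(sample(enriched, cfg$n_informative))
  list(genes = genes, enriched = enriched, informative = informative)
}

# Marginal frequencies of binary baseline covariates (UKB-like cohort table).
default_covariate_freqs <- function() {
  c(sex_male = 0.458, race_white = 0.936, never_smoker = 0.541,
    moderate_alcohol = 0.527, physically_active = 0.586,
    healthy_diet = 0.368, healthy_sleep = 0.370, hypertension = 0.563,
    type2_diabetes = 0.032, high_cholesterol = 0.200,
    social_isolation = 0.143, depression = 0.241, hearing_problems = 0.258,
    cvd_history = 0.090, traumatic_brain_injury = 0.001,
    parkinsons = 0.004, multiple_sclerosis = 0.002)
}

#' Simulate a genes-by-tissues bulk expression matrix
#'
#' Constructs a non-negative nTPM-like expression matrix in which exactly
#' `n_brain_enriched` genes satisfy the tissue-enrichment rule for the "brain"
#' column (expression at least `fold_threshold` times the maximum across all
#' other tissues and above the expression floor) and every other gene fails it
#' by construction.
#'
#' @param config A [sim_config()].
#' @param fold_threshold,expression_floor The enrichment rule parameters the
#'   matrix is constructed against (see [classify_tissue_enriched()]).
#' @return A tibble with a `gene` column and one column per tissue, carrying
#'   attributes `brain_enriched` (gene ids) and `tissues`.
#' @export
simulate_tissue_expression <- function(config, fold_threshold = 4,
                                       expression_floor = 1) {
  validate_sim_config(config)
  roles <- brain_gene_roles(config)
  genes <- roles$genes
  enriched <- roles$enriched
  set.seed(config$seed + 101L)
  tissues <- c("brain", "liver", "lung", "heart", "kidney", "muscle", "skin",
               "spleen", "pancreas", "testis", "colon", "adipose", "thyroid")
  n_other <- length(tissues) - 1L
  mat <- matrix(0, nrow = length(genes), ncol = length(tissues),
                dimnames = list(genes, tissues))
  for (g in genes) {
    if (g %in% enriched) {
      brain <- max(rlnorm(1, meanlog = log(40), sdlog = 0.6),
                   2 * expression_floor)
      # other tissues capped strictly below brain / (fold * 1.25)
      other <- runif(n_other, 0, brain / (fold_threshold * 1.25))
    } else {
      top <- rlnorm(1, meanlog = log(15), sdlog = 0.8)
      other <- runif(n_other, 0, top)
      other[sample.int(n_other, 1)] <- top
      # brain below fold_threshold * max(other): fails the rule for any floor
      brain <- runif(1, 0, 0.9 * fold_threshold) / fold_threshold * top
    }
    mat[g, ] <- c(brain, other)
  }
  out <- tibble::as_tibble(mat, rownames = "gene")
  attr(out, "brain_enriched") <- enriched
  attr(out, "tissues") <- tissues
  out
}

#' Simulate the proteomics matrix, cohort table and latent truth
#'
#' Draws chronological ages uniformly over the recruitment window and a latent
#' aging offset `delta ~ N(0, sigma_delta^2)`. Informative brain-enriched
#' proteins follow `a_j + b_j * (age + delta) + noise`; the remaining
#' brain-enriched proteins track age only; non-brain proteins are pure noise.
#' Dementia and death times come from (by default exponential) proportional
#' hazards driven by age, sex, APOE e4 count and the standardized offset, with
#' administrative censoring at the horizon. Dementia events are independently
#' thinned into Alzheimer's / vascular / other subtypes, so each subtype's
#' cause-specific hazard carries the same true log hazard ratio.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `proteins`: tibble, `participant` + one column per protein (NA =
#'     missing),
#'   * `cohort`: tibble of covariates, follow-up `time`, `event_type`
#'     (censored/dementia/death) and per-subtype event flags,
#'   * `truth`: list with `delta` (tibble of per-participant offsets),
#'     `informative_protein_ids`, and `true_log_hr`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed + 202L)
  n <- cfg$n_participants
  id <- sprintf("P%06d", seq_len(n))
  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  delta <- if (cfg$sigma_delta > 0) rnorm(n, 0, cfg$sigma_delta) else rep(0, n)
  delta_z <- if (cfg$sigma_delta > 0) delta / cfg$sigma_delta else rep(0, n)

  roles <- brain_gene_roles(cfg)
  genes <- roles$genes
  enr_pick <- roles$enriched
  informative <- roles$informative
  age_only <- setdiff(enr_pick, informative)

  set.seed(cfg$seed + 404L)
  a <- rnorm(cfg$n_proteins, 0, 2)
  b <- rlnorm(cfg$n_proteins, meanlog = log(0.1), sdlog = 0.4)
  names(a) <- names(b) <- genes
  prot <- matrix(rnorm(n * cfg$n_proteins, 0, cfg$protein_noise_sd),
                 nrow = n, dimnames = list(NULL, genes))
  for (g in informative) prot[, g] <- prot[, g] + a[g] + b[g] * (age + delta)
  for (g in age_only)    prot[, g] <- prot[, g] + a[g] + b[g] * age
  noise_genes <- setdiff(genes, enr_pick)
  for (g in noise_genes) prot[, g] <- prot[, g] + a[g]
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(n * cfg$n_proteins) < cfg$missing_rate, nrow = n)
    prot[miss] <- NA_real_
  }
  proteins <- dplyr::bind_cols(tibble::tibble(participant = id),
                               tibble::as_tibble(prot))

  # baseline covariates: Table-1-like marginals, drawn independently
  fr <- default_covariate_freqs()
  cov_bin <- purrr::map(fr, ~ rbinom(n, 1L, .x))
  education <- sample(c("low", "medium", "high"), n, replace = TRUE,
                      prob = c(0.350, 0.176, 0.474))
  prs <- sample(c("low", "medium", "high"), n, replace = TRUE,
                prob = c(1, 1, 1) / 3)
  apoe <- sample(0:2, n, replace = TRUE, prob = cfg$apoe_freqs)
  bmi <- rnorm(n, 27.5, 4.81)
  townsend <- rnorm(n, -1.2, 3.19)
  no2 <- rnorm(n, 29.4, 9.31)
  pm25 <- rnorm(n, 10.0, 1.07)

  # survival: cause-specific proportional hazards with administrative censoring
  lp_dem <- cfg$age_log_hr * (age - 55) + cfg$sex_log_hr * cov_bin$sex_male +
    cfg$apoe_log_hr * apoe + cfg$log_hr_per_sd_gap * delta_z
  lp_death <- 0.09 * (age - 55) + 0.3 * cov_bin$sex_male +
    cfg$death_log_hr_per_sd_gap * delta_z
  shape <- cfg$weibull_shape
  t_dem <- if (is.null(cfg$log_hr_late)) {
    (rexp(n) / (cfg$baseline_hazard * exp(lp_dem)))^(1 / shape)
  } else {
    # piecewise exposure effect: log-HR switches at hr_change_time
    rate1 <- cfg$baseline_hazard * exp(lp_dem)
    lp2 <- lp_dem + (cfg$log_hr_late - cfg$log_hr_per_sd_gap) * delta_z
    rate2 <- cfg$baseline_hazard * exp(lp2)
    t1 <- rexp(n) / rate1
    ifelse(t1 < cfg$hr_change_time, t1, cfg$hr_change_time + rexp(n) / rate2)
  }
  t_death <- (rexp(n) / (cfg$death_hazard * exp(lp_death)))^(1 / shape)
  time <- pmin(t_dem, t_death, cfg$censoring_horizon)
  event_type <- dplyr::case_when(
    t_dem <= time & t_dem <= t_death & t_dem < cfg$censoring_horizon ~ "dementia",
    t_death <= time & t_death < cfg$censoring_horizon ~ "death",
    TRUE ~ "censored"
  )
  subtype_draw <- runif(n)
  dem <- event_type == "dementia"
  event_all_cause <- as.integer(dem)
  event_ad <- as.integer(dem & subtype_draw < cfg$ad_fraction)
  event_vascular <- as.integer(
    dem & subtype_draw >= cfg$ad_fraction &
      subtype_draw < cfg$ad_fraction + cfg$vascular_fraction)

  cohort <- tibble::tibble(
    participant = id, age = age,
    sex_male = cov_bin$sex_male, race_white = cov_bin$race_white,
    education = education, townsend = townsend,
    townsend_high = as.integer(townsend >= median(townsend)),
    bmi = bmi, never_smoker = cov_bin$never_smoker,
    moderate_alcohol = cov_bin$moderate_alcohol,
    physically_active = cov_bin$physically_active,
    healthy_diet = cov_bin$healthy_diet, healthy_sleep = cov_bin$healthy_sleep,
    social_isolation = cov_bin$social_isolation, depression = cov_bin$depression,
    hearing_problems = cov_bin$hearing_problems,
    hypertension = cov_bin$hypertension,
    type2_diabetes = cov_bin$type2_diabetes,
    high_cholesterol = cov_bin$high_cholesterol,
    traumatic_brain_injury = cov_bin$traumatic_brain_injury,
    cvd_history = cov_bin$cvd_history,
    parkinsons = cov_bin$parkinsons,
    multiple_sclerosis = cov_bin$multiple_sclerosis,
    no2 = no2, pm25 = pm25,
    apoe_e4_count = apoe, prs_tertile = prs,
    time = time, event_type = event_type,
    event_all_cause = event_all_cause, event_ad = event_ad,
    event_vascular = event_vascular
  )
  if (cfg$covariate_missing_rate > 0) {
    for (v in c("bmi", "education", "townsend")) {
      hit <- runif(n) < cfg$covariate_missing_rate
      cohort[[v]][hit] <- NA
    }
    cohort$townsend_high[is.na(cohort$townsend)] <- NA_integer_
  }

  truth <- list(
    delta = tibble::tibble(participant = id, delta = delta, delta_z = delta_z),
    informative_protein_ids = informative,
    brain_enriched_ids = enr_pick,
    true_log_hr = cfg$log_hr_per_sd_gap
  )
  list(proteins = proteins, cohort = cohort, truth = truth)
}

# Per-SD-of-delta effects on the standardized volume scale; signs follow the
# atrophy pattern (global/cortical gray matter and hippocampus shrink, white
# matter hyperintensity and ventricular CSF expand with faster brain aging).
default_volume_effects <- function() {
  c(total_brain = -0.028, white_matter = 0.049, gray_matter = -0.090,
    cortical_gray_matter = -0.102, wmh = 0.084, ventricular_csf = 0.067,
    left_hippocampus = -0.032, right_hippocampus = 0,
    left_hippocampal_gm = 0, right_hippocampal_gm = 0)
}

volume_scale_table <- function() {
  tibble::tribble(
    ~phenotype, ~mu, ~sigma, ~age_slope,
    "total_brain", 1150000, 110000, -0.030,
    "white_matter", 540000, 60000, -0.010,
    "gray_matter", 610000, 55000, -0.035,
    "cortical_gray_matter", 480000, 45000, -0.035,
    "ventricular_csf", 39000, 8000, 0.040,
    "left_hippocampus", 3900, 400, -0.020,
    "right_hippocampus", 3900, 400, -0.020,
    "left_hippocampal_gm", 3200, 350, -0.020,
    "right_hippocampal_gm", 3200, 350, -0.020
  )
}

#' Simulate MRI volume phenotypes for an imaging subsample
#'
#' Draws an imaging subsample (default 8% of the cohort) and generates ten
#' brain-volume phenotypes in cubic millimetres as linear functions of age and
#' the standardized latent aging offset, plus image-related confounders (head
#' size scaling, three head-position coordinates, table position, imaging
#' centre) injected additively and independent noise. White-matter
#' hyperintensity (WMH) volume is generated log-normal, hence strictly
#' positive and right-skewed; its linear structure lives on the log scale.
#'
#' @param cohort,truth Elements of a [simulate_cohort()] result.
#' @param config The same [sim_config()].
#' @param delta_effects Named vector of per-SD effects of the aging offset on
#'   each standardized phenotype (WMH on the log scale).
#' @param confounder_strength Multiplier on all confounder effects; 0 makes
#'   residualization a pure centring/scaling operation.
#' @return Tibble with participant id, `interval_years`, confounder columns
#'   (`head_size`, `pos_x`, `pos_y`, `pos_z`, `table_pos`, `center`) and one
#'   column per phenotype, in mm^3.
#' @export
simulate_neuroimaging <- function(cohort, truth, config,
                                  delta_effects = default_volume_effects(),
                                  confounder_strength = 1) {
  validate_sim_config(config)
  stopifnot(all(names(default_volume_effects()) %in% names(delta_effects)))
  set.seed(config$seed + 505L)
  n_img <- max(2L, round(config$imaging_fraction * nrow(cohort)))
  pick <- sort(sample.int(nrow(cohort), n_img))
  sub <- cohort[pick, c("participant", "age")]
  dz <- truth$delta$delta_z[pick]
  head_size <- rnorm(n_img, 1, 0.1)
  pos <- matrix(rnorm(n_img * 4), ncol = 4)
  center <- sample(c("siteA", "siteB", "siteC"), n_img, replace = TRUE)
  center_off <- c(siteA = 0, siteB = 0.3, siteC = -0.2)[center]
  conf_lat <- confounder_strength *
    (2 * (head_size - 1) + 0.1 * rowSums(pos) + center_off)
  age_c <- sub$age - 55

  scales <- volume_scale_table()
  out <- tibble::tibble(
    participant = sub$participant,
    interval_years = pmax(0.5, rnorm(n_img, 9.1, 2)),
    head_size = head_size,
    pos_x = pos[, 1], pos_y = pos[, 2], pos_z = pos[, 3], table_pos = pos[, 4],
    center = center
  )
  for (i in seq_len(nrow(scales))) {
    ph <- scales$phenotype[i]
    latent <- scales$age_slope[i] * age_c + delta_effects[[ph]] * dz +
      conf_lat + rnorm(n_img)
    out[[ph]] <- pmax(scales$mu[i] + scales$sigma[i] * latent, 1)
  }
  log_wmh <- 8.3 + 0.6 * (0.04 * age_c + delta_effects[["wmh"]] * dz +
                            conf_lat + rnorm(n_img))
  out$wmh <- exp(log_wmh)
  out
}

#' Simulate predicted ages from a nonlinearly age-biased clock
#'
#' Emulates the systematic bias of age clocks: regression to the mean (slope
#' below 1 against chronological age) plus a smooth quadratic distortion,
#' with independent prediction noise. This is the canonical input for
#' validating that local-regression detrending removes the bias and leaves a
#' gap uncorrelated with chronological age (and that skipping the detrending
#' step fails that check).
#'
#' @param n Number of participants.
#' @param age_range Chronological age window, years.
#' @param slope Linear bias slope against age (1 = unbiased).
#' @param quad Quadratic bias coefficient (years^-1) around the window centre.
#' @param noise_sd SD of prediction noise, years.
#' @param seed Integer seed.
#' @return Tibble: participant, age, predicted_age.
#' @export
simulate_biased_predictions <- function(n = 45000L, age_range = c(40, 70),
                                        slope = 0.75, quad = 0.012,
                                        noise_sd = 4, seed = 1L) {
  set.seed(seed)
  centre <- mean(age_range)
  age <- runif(n, age_range[1], age_range[2])
  pred <- centre + slope * (age - centre) + quad * (age - centre)^2 +
    rnorm(n, 0, noise_sd)
  tibble::tibble(participant = sprintf("P%06d", seq_len(n)),
                 age = age, predicted_age = pred)
}

#' Write all simulated inputs as plain-text files
#'
#' Emits the expression matrix (TSV), proteomics matrix (CSV, empty cell =
#' missing), cohort table (CSV), imaging volumes (CSV), latent truth (CSV) and
#' a data dictionary describing every column.
#'
#' @param sim Result of [simulate_cohort()].
#' @param expr Result of [simulate_tissue_expression()].
#' @param volumes Result of [simulate_neuroimaging()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, expr, volumes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "tissue_expression.tsv"),
    proteins = file.path(dir, "proteomics.csv"),
    cohort = file.path(dir, "cohort.csv"),
    volumes = file.path(dir, "volumes.csv"),
    truth = file.path(dir, "truth.csv"),
    dictionary = file.path(dir, "data_dictionary.tsv")
  )
  readr::write_tsv(expr, paths[["expression"]])
  readr::write_csv(sim$proteins, paths[["proteins"]], na = "")
  readr::write_csv(sim$cohort, paths[["cohort"]], na = "")
  readr::write_csv(volumes, paths[["volumes"]], na = "")
  readr::write_csv(sim$truth$delta, paths[["truth"]])
  dict <- tibble::tibble(
    table = c("tissue_expression", "proteomics", "cohort", "cohort", "volumes",
              "volumes", "truth"),
    column = c("gene + one column per tissue (nTPM-like)",
               "participant + one column per protein (NPX-like; empty = missing)",
               "participant, age, covariates (see sim_config docs)",
               "time (years), event_type, event_all_cause/ad/vascular flags",
               "participant, interval_years, confounders (head_size, pos_*, center)",
               "one column per volume phenotype (mm^3); wmh log-normal",
               "participant, delta (years), delta_z (standardized)")
  )
  readr::write_tsv(dict, paths[["dictionary"]])
  invisible(paths)
}
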