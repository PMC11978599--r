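#' Baseline characteristics by gap quartile
#'
#' Summarizes baseline covariates across the four quartiles of non-extreme
#' agers: mean (SD) for continuous variables with an ANOVA F-test, percentage
#' for binary/categorical variables with a chi-square test.
#'
#' @param data Cohort joined to a classified gap table (needs `quartile`).
#' @param continuous,categorical Variables to summarize (defaults cover the
#'   generator's columns found in `data`).
#' @return Tibble: variable, level, overall and per-quartile summary, p_value.
#' @export
baseline_by_quartile <- function(data,
                                 continuous = c("age", "bmi", "townsend",
                                                "no2", "pm25"),
                                 categorical = c("sex_male", "race_white",
                                                 "education", "never_smoker",
                                                 "moderate_alcohol",
                                                 "physically_active",
                                                 "healthy_diet",
                                                 "healthy_sleep",
                                                 "hypertension",
                                                 "type2_diabetes",
                                                 "high_cholesterol",
                                                 "social_isolation",
                                                 "depression",
                                                 "hearing_problems",
                                                 "cvd_history",
                                                 "apoe_e4_count",
                                                 "prs_tertile")) {
  stopifnot("quartile" %in% names(data))
  dd <- data[!is.na(data$quartile), ]
  q <- factor(dd$quartile)
  fmt <- function(m, s) sprintf("%.1f (%.2f)", m, s)
  rows <- list()
  for (v in intersect(continuous, names(dd))) {
    x <- dd[[v]]
    ok <- !is.na(x)
    p <- tryCatch(summary(stats::aov(x[ok] ~ q[ok]))[[1]][["Pr(>F)"]][1],
                  error = function(e) NA_real_)
    cells <- c(fmt(mean(x, na.rm = TRUE), sd(x, na.rm = TRUE)),
               purrr::map_chr(levels(q), ~ fmt(mean(x[q == .x], na.rm = TRUE),
                                               sd(x[q == .x], na.rm = TRUE))))
    rows[[v]] <- tibble::tibble(variable = v, level = NA_character_,
                                total = cells[1], q1 = cells[2], q2 = cells[3],
                                q3 = cells[4], q4 = cells[5], p_value = p)
  }
  for (v in intersect(categorical, names(dd))) {
    x <- factor(dd[[v]])
    ok <- !is.na(x)
    p <- tryCatch(stats::chisq.test(table(x[ok], q[ok]))$p.value,
                  error = function(e) NA_real_)
    for (l in levels(x)) {
      pct <- function(idx) sprintf("%.1f", 100 * mean(x[idx] == l, na.rm = TRUE))
      rows[[paste(v, l)]] <- tibble::tibble(
        variable = v, level = l, total = pct(ok),
        q1 = pct(ok & q == "1"), q2 = pct(ok & q == "2"),
        q3 = pct(ok & q == "3"), q4 = pct(ok & q == "4"), p_value = p)
    }
  }
  dplyr::bind_rows(rows)
}

read_pipeline_inputs <- function(config) {
  paths <- config$inputs
  need <- c("expression", "proteins", "cohort")
  miss <- setdiff(need, names(paths))
  if (length(miss) > 0) {
    abort(paste("config lacks a simulation block and input path(s):",
                paste(miss, collapse = ", ")))
  }
  list(
    expr = readr::read_tsv(paths$expression, show_col_types = FALSE),
    sim = list(
      proteins = readr::read_csv(paths$proteins, show_col_types = FALSE),
      cohort = readr::read_csv(paths$cohort, show_col_types = FALSE),
      truth = NULL
    ),
    volumes = if (!is.null(paths$volumes)) {
      readr::read_csv(paths$volumes, show_col_types = FALSE)
    }
  )
}

#' Run the full brain-age pipeline from one configuration
#'
#' Executes simulate (or load) -> enrichment/QC -> clock -> gap -> survival
#' battery -> imaging associations -> report, writing tidy CSVs, a Markdown
#' report and a manifest (file checksums, seeds) into the output directory.
#' The global seed fans out to fixed per-stage seeds so adding a stage never
#' perturbs an earlier stage's random stream; the same config and seed
#' reproduce byte-identical outputs.
#'
#' @param config A list or path to a YAML file with elements `output_dir`,
#'   `seed`, and either `simulation` (arguments to [sim_config()]) or `inputs`
#'   (paths to expression/proteins/cohort/volumes files); optional blocks
#'   `clock` (`n_folds`, `boruta`, `params`), `gap` (`span`, `degree`),
#'   `survival` (`tiers`, `outcomes`), and `stages` (character vector to run).
#' @return Invisibly, a list of all stage results (including the manifest).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) abort("config needs `output_dir`")
  if (is.null(config$simulation) && is.null(config$inputs)) {
    abort("config needs a `simulation` block or an `inputs` block")
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_on <- function(s) is.null(config$stages) || s %in% config$stages
  log_stage <- function(s, ...) message(sprintf("[%s] ", s), ...)
  results <- list(seed = seed)
  written <- character()
  emit <- function(tab, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tibble::as_tibble(tab), path, na = "")
    written <<- c(written, path)
  }

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$simulation)) {
    log_stage("simulate", "generating synthetic cohort")
    sim_args <- config$simulation
    sim_args$seed <- as.integer(sim_args$seed %||% seed)
    cfg <- do.call(sim_config, sim_args)
    expr <- simulate_tissue_expression(cfg)
    sim <- simulate_cohort(cfg)
    volumes <- simulate_neuroimaging(sim$cohort, sim$truth, cfg)
    if (stage_on("simulate")) {
      write_simulation(sim, expr, volumes, file.path(out_dir, "inputs"))
    }
  } else {
    log_stage("load", "reading user-supplied inputs")
    inp <- read_pipeline_inputs(config)
    expr <- inp$expr
    sim <- inp$sim
    volumes <- inp$volumes
  }
  cohort <- sim$cohort

  # --- enrichment & QC ------------------------------------------------------
  log_stage("enrich", "classifying brain-enriched proteins and applying QC")
  calls <- classify_tissue_enriched(expr, "brain")
  qc <- qc_filter_proteins(sim$proteins,
                           missing_threshold = config$qc$max_missing %||% 0.10)
  imputed <- impute_protein_values(qc$proteins)
  panel <- select_brain_enriched(imputed, calls)
  emit(calls, "enrichment_calls")
  emit(qc$report, "qc_report")
  if (ncol(panel) < 3L) abort("fewer than 2 brain-enriched proteins: no clock")

  # --- clock ----------------------------------------------------------------
  log_stage("clock", sprintf("fitting clock on %d proteins", ncol(panel) - 1L))
  clock_cfg <- config$clock %||% list()
  clock <- fit_clock(panel, cohort$age,
                     params = clock_cfg$params %||% list(),
                     n_folds = clock_cfg$n_folds %||% 5L, seed = seed + 1L)
  results$clock <- clock
  if (isTRUE(clock_cfg$boruta %||% TRUE)) {
    log_stage("clock", "Boruta shadow-feature selection")
    sel <- boruta_select(panel, cohort$age, seed = seed + 2L)
    results$boruta <- sel
    if (length(sel$confirmed) >= 2) {
      clock_sel <- fit_clock(panel[c("participant", sel$confirmed)],
                             cohort$age,
                             params = clock_cfg$params %||% list(),
                             n_folds = clock_cfg$n_folds %||% 5L,
                             seed = seed + 1L)
      results$clock_selected <- clock_sel
    }
    emit(sel$history, "boruta_history")
  }
  final_clock <- results$clock_selected %||% clock
  shap <- shapley_importance(final_clock, panel)
  metrics <- evaluate_clock(final_clock$predictions$predicted_age, cohort$age,
                            subgroups = cohort[intersect(
                              c("sex_male", "education"), names(cohort))])
  emit(shap, "shap_importance")
  emit(metrics, "clock_metrics")

  # --- gap ------------------------------------------------------------------
  log_stage("gap", "LOESS detrending and extreme-ager classification")
  gap_cfg <- config$gap %||% list()
  gaps <- compute_gap(final_clock$predictions, age = "age",
                      span = gap_cfg$span %||% (2 / 3),
                      degree = gap_cfg$degree %||% 1L) |>
    classify_agers()
  decor <- decorrelation_check(gaps)
  results$gaps <- gaps
  results$decorrelation <- decor
  # all-protein clock gap for the pre-selection sensitivity analysis
  gaps_all <- compute_gap(clock$predictions, age = "age",
                          span = gap_cfg$span %||% (2 / 3),
                          degree = gap_cfg$degree %||% 1L)
  emit(gaps, "gap")
  emit(decor, "decorrelation_check")

  # --- survival battery -----------------------------------------------------
  log_stage("survival", "Cox tiers, spline, diagnostics, competing risks")
  analysis <- prepare_covariates(cohort) |>
    dplyr::inner_join(
      tibble::as_tibble(gaps)[c("participant", "gap_z", "ager_class",
                                "quartile")],
      by = "participant") |>
    dplyr::left_join(
      dplyr::rename(tibble::as_tibble(gaps_all)[c("participant", "gap_z")],
                    gap_z_all = "gap_z"),
      by = "participant")
  emit(baseline_by_quartile(analysis), "baseline_by_quartile")
  tiers <- config$survival$tiers %||% c("M1", "M2", "M3", "M4")
  outcomes <- config$survival$outcomes %||% c("all_cause", "ad", "vascular")
  hr_rows <- list()
  for (oc in outcomes) {
    for (ti in tiers) {
      for (ex in c("gap_z", "ager_class")) {
        res <- tryCatch(fit_cox(analysis, model_spec(ti, oc, ex)),
                        error = function(e) NULL)
        if (!is.null(res)) hr_rows[[paste(oc, ti, ex)]] <- res
      }
    }
  }
  hr_table <- dplyr::bind_rows(hr_rows)
  results$hr_table <- hr_table
  emit(hr_table, "hr_models")

  primary_spec <- model_spec("M3", "all_cause", "gap_z")
  base_fit <- tryCatch(fit_cox(analysis, primary_spec),
                       error = function(e) NULL)
  if (!is.null(base_fit)) {
    ph <- tryCatch(schoenfeld_check(base_fit), error = function(e) NULL)
    if (!is.null(ph)) {
      results$schoenfeld <- ph
      emit(tibble::tibble(stat = ph$stat, df = ph$df, p = ph$p),
           "schoenfeld_test")
      emit(ph$residuals, "schoenfeld_residuals")
    }
    rcs <- tryCatch(rcs_nonlinearity(analysis, primary_spec),
                    error = function(e) NULL)
    if (!is.null(rcs)) {
      results$rcs <- rcs
      emit(rcs$curve, "spline_hr_curve")
      emit(glance(rcs), "spline_nonlinearity")
    }
    fg <- tryCatch(fine_gray_fit(analysis, primary_spec),
                   error = function(e) NULL)
    if (!is.null(fg)) emit(fg, "fine_gray")
    inter_rows <- list()
    for (mod in intersect(c("never_smoker", "moderate_alcohol",
                            "physically_active", "healthy_diet",
                            "healthy_sleep", "apoe_e4_count", "prs_tertile"),
                          names(analysis))) {
      si <- tryCatch(subgroup_interactions(analysis, primary_spec, mod),
                     error = function(e) NULL)
      if (!is.null(si) && nrow(si$strata) > 0) {
        si$strata$p_interaction <- si$p_interaction
        inter_rows[[mod]] <- si$strata
      }
    }
    if (length(inter_rows) > 0) {
      results$interactions <- dplyr::bind_rows(inter_rows)
      emit(results$interactions, "subgroup_forest")
    }
    sens <- tryCatch(sensitivity_suite(analysis, primary_spec,
                                       alt_gap = "gap_z_all"),
                     error = function(e) NULL)
    if (!is.null(sens)) emit(sens, "sensitivity")
  }

  # --- imaging --------------------------------------------------------------
  if (!is.null(volumes)) {
    log_stage("imaging", "residualizing volumes and fitting associations")
    resid <- residualize_volumes(volumes)
    beta_tab <- dplyr::bind_rows(
      tryCatch(volume_association(resid, gaps, analysis, "gap_z",
                                  volumes = volumes),
               error = function(e) NULL),
      tryCatch(volume_association(resid, gaps, analysis, "ager_class",
                                  volumes = volumes),
               error = function(e) NULL))
    results$imaging <- beta_tab
    if (nrow(beta_tab) > 0) emit(beta_tab, "imaging_betas")
  }

  # --- report & manifest ----------------------------------------------------
  log_stage("report", "writing report and manifest")
  report <- c(
    "# Brain age gap pipeline report", "",
    sprintf("- participants: %d", nrow(cohort)),
    sprintf("- proteins after QC: %d (brain-enriched panel: %d)",
            ncol(qc$proteins) - 1L, ncol(panel) - 1L),
    sprintf("- clock out-of-fold R^2: %.3f, RMSE: %.2f y",
            metrics$r_squared[1], metrics$rmse[1]),
    sprintf("- gap-age decorrelation |r| = %.2e (pass: %s)", decor$abs_r,
            decor$pass),
    sprintf("- extreme agers: %d young / %d old of %d",
            sum(gaps$ager_class == "extreme_young"),
            sum(gaps$ager_class == "extreme_old"), nrow(gaps)),
    sprintf("- Cox rows: %d; seed: %d", nrow(hr_table), seed),
    "", "See the CSV files alongside this report for all tables.")
  writeLines(report, file.path(out_dir, "report.md"))
  written <- c(written, file.path(out_dir, "report.md"))
  manifest <- tibble::tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written)),
    bytes = file.size(written),
    seed = seed
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  results$manifest <- manifest
  invisible(results)
}
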