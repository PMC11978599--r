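covariate_tiers <- local({
  m1 <- c("age", "sex_male")
  m2 <- c(m1, "race_white", "education", "townsend_high", "bmi",
          "never_smoker", "moderate_alcohol", "physically_active",
          "healthy_sleep", "healthy_diet", "social_isolation", "depression",
          "hearing_problems", "hypertension", "type2_diabetes",
          "high_cholesterol", "traumatic_brain_injury", "cvd_history",
          "no2", "pm25")
  list(M1 = m1, M2 = m2, M3 = c(m2, "apoe_e4_count"),
       M4 = c(m2, "prs_tertile"))
})

#' Specify a dementia association model
#'
#' Encodes the covariate tiers of the association battery: Model 1 adjusts
#' for chronological age and sex; Model 2 adds race, education, Townsend
#' deprivation, BMI, lifestyle factors, comorbidities and air pollution;
#' Model 3 adds the APOE e4 allele count to Model 2; Model 4 adds the
#' Alzheimer's polygenic-risk-score tertile to Model 2.
#'
#' @param tier One of "M1".."M4".
#' @param outcome One of "all_cause", "ad", "vascular".
#' @param exposure "gap_z" (per-SD continuous), "ager_class" (extreme-ager
#'   contrasts vs non-extreme), or "rcs" (restricted cubic spline).
#' @return List of class `model_spec` with the materialized covariate list.
#' @export
model_spec <- function(tier = c("M1", "M2", "M3", "M4"),
                       outcome = c("all_cause", "ad", "vascular"),
                       exposure = c("gap_z", "ager_class", "rcs")) {
  tier <- match.arg(tier)
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  structure(list(tier = tier, outcome = outcome, exposure = exposure,
                 covariates = covariate_tiers[[tier]]),
            class = "model_spec")
}

#' Prepare covariates for the association models
#'
#' Continuous covariates are mean-imputed; categorical covariates get an
#' explicit "missing" level. For each covariate with any missingness a logical
#' `<name>_missing` flag is added, plus `any_missing`, which drives the
#' complete-case sensitivity analysis.
#'
#' @param cohort Cohort tibble (e.g. from [simulate_cohort()]).
#' @param continuous,categorical Covariate names to treat as continuous /
#'   categorical; defaults cover the generator's columns present in `cohort`.
#' @return The cohort with imputed covariates and missingness flags.
#' @export
prepare_covariates <- function(cohort,
                               continuous = c("age", "bmi", "townsend",
                                              "no2", "pm25"),
                               categorical = c("education", "prs_tertile",
                                               "townsend_high")) {
  continuous <- intersect(continuous, names(cohort))
  categorical <- intersect(categorical, names(cohort))
  flags <- character()
  for (v in continuous) {
    if (all(is.na(cohort[[v]]))) abort(sprintf("covariate '%s' entirely missing", v))
    miss <- is.na(cohort[[v]])
    if (any(miss)) {
      cohort[[paste0(v, "_missing")]] <- miss
      cohort[[v]][miss] <- mean(cohort[[v]], na.rm = TRUE)
      flags <- c(flags, paste0(v, "_missing"))
    }
  }
  for (v in categorical) {
    if (all(is.na(cohort[[v]]))) abort(sprintf("covariate '%s' entirely missing", v))
    miss <- is.na(cohort[[v]])
    if (any(miss)) {
      cohort[[paste0(v, "_missing")]] <- miss
      x <- as.character(cohort[[v]])
      x[miss] <- "missing"
      cohort[[v]] <- x
      flags <- c(flags, paste0(v, "_missing"))
    }
  }
  cohort$any_missing <- if (length(flags) > 0) {
    Reduce(`|`, cohort[flags])
  } else rep(FALSE, nrow(cohort))
  cohort
}

event_column <- function(outcome) paste0("event_", outcome)

surv_formula <- function(exposure_terms, covariates, response =
                           "survival::Surv(time, event)") {
  as.formula(paste(response, "~",
                   paste(c(exposure_terms, covariates), collapse = " + ")))
}

cox_result_row <- function(fit, term_names, spec, label = NULL,
                           model = "cox") {
  s <- summary(fit)
  co <- s$coefficients
  idx <- match(term_names, rownames(co))
  if (anyNA(idx)) abort("exposure term(s) missing from the fitted model")
  est <- co[idx, "coef"]
  se <- co[idx, "se(coef)"]
  tibble::tibble(
    term = term_names, estimate = unname(est), se = unname(se),
    hr = exp(unname(est)),
    conf.low = exp(unname(est) - 1.96 * unname(se)),
    conf.high = exp(unname(est) + 1.96 * unname(se)),
    p_value = unname(co[idx, "Pr(>|z|)"]),
    tier = spec$tier, outcome = spec$outcome, exposure = spec$exposure,
    model = model, stratum = label %||% NA_character_,
    n = s$n, n_events = s$nevent
  )
}

#' Fit a covariate-tiered Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) for the brain age
#' gap exposure under the spec's covariate tier and outcome. For the
#' `ager_class` exposure, two contrasts are returned (extreme young and
#' extreme old, each vs the non-extreme reference).
#'
#' @param data Analysis tibble: gap columns joined to the cohort (must contain
#'   `time`, the outcome's event flag, the exposure and all tier covariates).
#' @param spec A [model_spec()].
#' @param min_events Refuse to fit with fewer events (guards against unstable
#'   estimates; lower it only for toy data).
#' @return Tibble with one row per exposure term (estimate = log-HR, se, hr,
#'   95% CI, p); the `coxph` fit is attached as attribute `"fit"`.
#' @export
fit_cox <- function(data, spec, min_events = 10L) {
  ev <- event_column(spec$outcome)
  if (!ev %in% names(data)) abort(sprintf("missing event column '%s'", ev))
  data$event <- data[[ev]]
  n_events <- sum(data$event)
  if (n_events == 0) abort("no events for this outcome")
  if (n_events < min_events) abort("too few events for this outcome")
  covs <- intersect(spec$covariates, names(data))
  if (spec$exposure == "rcs") {
    abort("use rcs_nonlinearity() for the spline exposure")
  }
  exposure_var <- spec$exposure
  if (exposure_var == "ager_class") {
    data$ager_class <- stats::relevel(factor(data$ager_class),
                                      ref = "non_extreme")
  }
  fit <- survival::coxph(surv_formula(exposure_var, covs), data = data,
                         ties = "efron", model = TRUE, x = TRUE)
  terms <- if (spec$exposure == "ager_class") {
    c("ager_classextreme_young", "ager_classextreme_old")
  } else "gap_z"
  out <- cox_result_row(fit, terms, spec)
  attr(out, "fit") <- fit
  out
}

#' Restricted cubic spline basis (natural spline, linear tails)
#'
#' Harrell's truncated-power construction: `k` knots yield `k - 1` basis
#' columns, the first the identity and the rest cubic terms constrained so the
#' function is linear beyond the boundary knots; nonlinear terms are
#' normalized by the squared boundary-knot span.
#'
#' @param x Numeric vector.
#' @param knots Increasing knot locations (at least 3, no ties).
#' @return Matrix with `length(knots) - 1` columns (`rcs1`..), `knots`
#'   attribute attached.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(knots)
  k <- length(knots)
  if (k < 3) abort("need at least 3 knots")
  if (any(diff(knots) <= 0)) abort("knot collapse: knots must be distinct")
  norm <- (knots[k] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1L)
  B[, 1] <- x
  for (j in seq_len(k - 2L)) {
    B[, j + 1L] <- (pos3(x - knots[j]) -
      pos3(x - knots[k - 1L]) * (knots[k] - knots[j]) /
        (knots[k] - knots[k - 1L]) +
      pos3(x - knots[k]) * (knots[k - 1L] - knots[j]) /
        (knots[k] - knots[k - 1L])) / norm
  }
  colnames(B) <- paste0("rcs", seq_len(k - 1L))
  attr(B, "knots") <- knots
  B
}

joint_wald <- function(fit, terms) {
  b <- coef(fit)[terms]
  V <- vcov(fit)[terms, terms, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  list(stat = stat, df = length(terms),
       p = pchisq(stat, df = length(terms), lower.tail = FALSE))
}

#' Test nonlinearity of the gap-dementia association with a restricted cubic
#' spline
#'
#' Expands the gap z-score in a 5-knot restricted cubic spline (knots at the
#' 5th, 27.5th, 50th, 72.5th and 95th sample percentiles by default, giving 4
#' basis columns), fits the Cox model with the spec's covariates, and tests
#' the 3 nonlinear coefficients jointly by a Wald test. The hazard-ratio curve
#' is referenced at gap z = 0, so `hr_curve(0)` is exactly 1.
#'
#' @param data Analysis tibble as in [fit_cox()].
#' @param spec A [model_spec()] (its covariate tier is used).
#' @param knot_probs Percentile locations of the knots.
#' @param ref Reference exposure value for the HR curve.
#' @return List of class `rcs_result`: `curve` (tibble gap_z, hr, conf.low,
#'   conf.high), `hr_curve` (vectorized function), `p_nonlinear`, `knots`,
#'   and the underlying fit.
#' @export
rcs_nonlinearity <- function(data, spec,
                             knot_probs = c(5, 27.5, 50, 72.5, 95) / 100,
                             ref = 0) {
  ev <- event_column(spec$outcome)
  data$event <- data[[ev]]
  if (sum(data$event) < 10) abort("fewer than 10 events for this outcome")
  knots <- quantile(data$gap_z, knot_probs, names = FALSE, type = 7)
  if (any(diff(knots) <= 0)) abort("knot collapse: tied knot percentiles")
  B <- rcs_basis(data$gap_z, knots)
  covs <- intersect(spec$covariates, names(data))
  df <- dplyr::bind_cols(data, tibble::as_tibble(B))
  fit <- survival::coxph(surv_formula(colnames(B), covs), data = df,
                         ties = "efron", model = TRUE, x = TRUE)
  nl_terms <- colnames(B)[-1]
  wald <- joint_wald(fit, nl_terms)
  beta <- coef(fit)[colnames(B)]
  V <- vcov(fit)[colnames(B), colnames(B)]
  hr_curve <- function(z) {
    D <- rcs_basis(z, knots) - rcs_basis(rep(ref, length(z)), knots)
    exp(drop(D %*% beta))
  }
  zs <- seq(quantile(data$gap_z, 0.01), quantile(data$gap_z, 0.99),
            length.out = 200)
  D <- rcs_basis(zs, knots) - rcs_basis(rep(ref, length(zs)), knots)
  eta <- drop(D %*% beta)
  se <- sqrt(rowSums((D %*% V) * D))
  structure(list(
    curve = tibble::tibble(gap_z = zs, hr = exp(eta),
                           conf.low = exp(eta - 1.96 * se),
                           conf.high = exp(eta + 1.96 * se)),
    hr_curve = hr_curve, p_nonlinear = wald$p, wald_stat = wald$stat,
    knots = knots, fit = fit, tier = spec$tier, outcome = spec$outcome
  ), class = "rcs_result")
}

#' @export
#' @method tidy rcs_result
tidy.rcs_result <- function(x, ...) x$curve

#' @export
#' @method glance rcs_result
glance.rcs_result <- function(x, ...) {
  tibble::tibble(p_nonlinear = x$p_nonlinear, wald_stat = x$wald_stat,
                 df = length(x$knots) - 2L, tier = x$tier, outcome = x$outcome)
}

#' Schoenfeld-residual check of proportional hazards
#'
#' Computes scaled Schoenfeld residuals at event times for the exposure term
#' and the standard correlation-with-time score test (Kaplan-Meier transform
#' of time by default), returning the residuals for plotting.
#'
#' @param fit A `coxph` fit or a [fit_cox()] result (its `"fit"` attribute is
#'   used).
#' @param term Model term to test.
#' @param transform Time transform for the test ("km", "rank" or "identity").
#' @return List: `stat` (chi-square), `df`, `p`, and `residuals` tibble
#'   (event time, scaled residual).
#' @export
schoenfeld_check <- function(fit, term = "gap_z", transform = "km") {
  if (!inherits(fit, "coxph")) fit <- attr(fit, "fit")
  if (is.null(fit)) abort("need a coxph fit or a fit_cox() result")
  if (fit$nevent < 20) abort("need at least 20 events for the PH check")
  zph <- survival::cox.zph(fit, transform = transform, terms = FALSE)
  if (!term %in% rownames(zph$table)) abort(sprintf("term '%s' not in model", term))
  row <- zph$table[term, ]
  list(stat = unname(row["chisq"]), df = unname(row["df"]),
       p = unname(row["p"]),
       residuals = tibble::tibble(time = zph$time,
                                  transformed_time = zph$x,
                                  residual = zph$y[, term]))
}

#' Fine-Gray subdistribution-hazard model for dementia with competing death
#'
#' Expands the data into Fine-Gray weighted risk sets, in which participants
#' who die remain at risk beyond their death time with
#' inverse-probability-of-censoring weights from the reverse Kaplan-Meier
#' curve, then maximizes the weighted Cox partial likelihood. With no
#' competing events the construction reduces exactly to the cause-specific
#' Cox model.
#'
#' @param data Analysis tibble including `event_type`
#'   (censored/dementia/death) and the outcome flags.
#' @param spec A [model_spec()].
#' @return Tibble as in [fit_cox()] with `model = "fine_gray"` (subdistribution
#'   HR); the weighted fit is attached as `"fit"`.
#' @export
fine_gray_fit <- function(data, spec) {
  ev <- event_column(spec$outcome)
  status <- factor(
    dplyr::case_when(data[[ev]] == 1 ~ "event",
                     data$event_type == "death" ~ "death",
                     TRUE ~ "censored"),
    levels = c("censored", "event", "death"))
  if (sum(status == "event") < 10) abort("fewer than 10 events for this outcome")
  covs <- intersect(spec$covariates, names(data))
  exposure <- if (spec$exposure == "ager_class") "ager_class" else "gap_z"
  if (exposure == "ager_class") {
    data$ager_class <- stats::relevel(factor(data$ager_class),
                                      ref = "non_extreme")
  }
  fg_vars <- unique(c(exposure, covs))
  dd <- data[c("time", fg_vars)]
  dd$fgstatus <- status
  fg <- survival::finegray(survival::Surv(time, fgstatus) ~ ., data = dd,
                           etype = "event")
  fg_formula <- surv_formula(exposure, covs,
                             response = "survival::Surv(fgstart, fgstop, fgstatus)")
  environment(fg_formula) <- environment()  # so `fg` is visible to model.frame
  fit <- survival::coxph(fg_formula, data = fg, weights = fg$fgwt,
                         ties = "efron", model = TRUE, x = TRUE)
  terms <- if (spec$exposure == "ager_class") {
    c("ager_classextreme_young", "ager_classextreme_old")
  } else "gap_z"
  out <- cox_result_row(fit, terms, spec, model = "fine_gray")
  attr(out, "fit") <- fit
  out
}

#' Subgroup hazard ratios and interaction test
#'
#' Fits the spec's Cox model separately within each level of a categorical
#' effect modifier (forest-plot table) and tests effect modification by a
#' joint Wald test on the gap-by-modifier interaction terms in the pooled
#' model.
#'
#' @param data Analysis tibble.
#' @param spec A [model_spec()] with the continuous gap exposure.
#' @param modifier Name of a categorical column with at least 2 levels.
#' @param min_events Strata with fewer events are flagged and excluded from
#'   the forest table (the interaction test still uses all data).
#' @return List: `strata` (per-level association rows), `p_interaction`,
#'   `interaction_df`, `flagged` (levels below the event floor).
#' @export
subgroup_interactions <- function(data, spec, modifier, min_events = 10L) {
  if (!modifier %in% names(data)) abort(sprintf("no column '%s'", modifier))
  lv <- sort(unique(as.character(data[[modifier]])))
  if (length(lv) < 2) abort("modifier needs at least 2 levels")
  covs <- setdiff(intersect(spec$covariates, names(data)), modifier)
  ev <- event_column(spec$outcome)
  strata <- list()
  flagged <- character()
  for (l in lv) {
    sub <- data[as.character(data[[modifier]]) == l, ]
    if (sum(sub[[ev]]) < min_events) {
      flagged <- c(flagged, l)
      next
    }
    sub_spec <- spec
    sub_spec$covariates <- covs
    row <- fit_cox(sub, sub_spec)
    row$stratum <- paste0(modifier, "=", l)
    strata[[l]] <- row
  }
  data$event <- data[[ev]]
  data$.mod <- factor(as.character(data[[modifier]]))
  pooled <- survival::coxph(
    surv_formula(c("gap_z * .mod"), covs), data = data, ties = "efron",
    model = TRUE, x = TRUE)
  int_terms <- grep("^gap_z:", names(coef(pooled)), value = TRUE)
  wald <- joint_wald(pooled, int_terms)
  list(strata = dplyr::bind_rows(strata), p_interaction = wald$p,
       interaction_df = wald$df, flagged = flagged)
}

#' Sensitivity analyses for the gap-dementia association
#'
#' Re-runs the Cox model under: (a) a 5-year landmark (participants with
#' follow-up beyond 5 years, clock restarted at year 5); (b) restriction to
#' participants aged 60 or older at baseline; (c) complete cases only (no
#' missing covariates, using the flags from [prepare_covariates()]); and
#' optionally (d) an alternative exposure column, e.g. the pre-selection
#' (all-protein) clock's gap. Scenarios that cannot run (too few events) are
#' reported with their reason.
#'
#' @param data Analysis tibble.
#' @param spec A [model_spec()].
#' @param alt_gap Optional name of an alternative gap z-score column.
#' @param landmark_years Landmark time in years.
#' @param min_age Age restriction cut-off.
#' @return Tibble of association rows with a `scenario` column; failed
#'   scenarios appear in the `skipped` attribute.
#' @export
sensitivity_suite <- function(data, spec, alt_gap = NULL, landmark_years = 5,
                              min_age = 60) {
  scenarios <- list(
    base = function(d) d,
    landmark_5y = function(d) {
      d <- d[d$time > landmark_years, ]
      d$time <- d$time - landmark_years
      d
    },
    age_60_plus = function(d) d[d$age >= min_age, ],
    complete_case = function(d) {
      if ("any_missing" %in% names(d)) d[!d$any_missing, ] else d
    }
  )
  if (!is.null(alt_gap)) {
    scenarios$alt_clock <- function(d) {
      d$gap_z <- d[[alt_gap]]
      d
    }
  }
  rows <- list()
  skipped <- character()
  for (nm in names(scenarios)) {
    res <- tryCatch({
      r <- fit_cox(scenarios[[nm]](data), spec)
      r$scenario <- nm
      r
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) skipped[nm] <- res else rows[[nm]] <- res
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}
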