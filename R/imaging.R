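volume_phenotypes <- function() {
  c("total_brain", "white_matter", "gray_matter", "cortical_gray_matter",
    "wmh", "ventricular_csf", "left_hippocampus", "right_hippocampus",
    "left_hippocampal_gm", "right_hippocampal_gm")
}

imaging_confounders <- function() {
  c("head_size", "pos_x", "pos_y", "pos_z", "table_pos", "center")
}

#' Residualize brain-volume phenotypes on image-related confounders
#'
#' White-matter hyperintensity volume is natural-log-transformed first (it is
#' right-skewed and must be strictly positive). Each phenotype is then
#' regressed by ordinary least squares on the head-size scaling factor, the
#' four position covariates and imaging-centre indicators, and the residuals
#' are standardized to mean 0 and SD 1. These scaled residuals are the
#' outcomes of the imaging association analysis.
#'
#' @param volumes Volume tibble (generator layout: participant, confounder
#'   columns, one column per phenotype in mm^3).
#' @param phenotypes,confounders Column subsets to use.
#' @return Long tibble: participant, phenotype, scaled_residual.
#' @export
residualize_volumes <- function(volumes, phenotypes = volume_phenotypes(),
                                confounders = imaging_confounders()) {
  phenotypes <- intersect(phenotypes, names(volumes))
  confounders <- intersect(confounders, names(volumes))
  if (anyNA(volumes[confounders])) abort("confounder columns must be complete")
  if ("wmh" %in% phenotypes) {
    bad <- which(volumes$wmh <= 0)
    if (length(bad) > 0) {
      abort(sprintf("non-positive WMH volume for participant(s): %s",
                    paste(head(volumes$participant[bad], 5), collapse = ", ")))
    }
  }
  X <- if (length(confounders) == 0) {
    matrix(1, nrow(volumes), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(
      as.formula(paste("~", paste(confounders, collapse = " + "))),
      data = volumes)
  }
  out <- purrr::map(phenotypes, function(ph) {
    y <- volumes[[ph]]
    if (ph == "wmh") y <- log(y)
    fit <- stats::lm.fit(X, y)
    r <- fit$residuals
    if (sd(r) < 1e-10) {
      abort(sprintf("phenotype '%s' is fully explained by confounders", ph))
    }
    tibble::tibble(participant = volumes$participant, phenotype = ph,
                   scaled_residual = (r - mean(r)) / sd(r))
  })
  dplyr::bind_rows(out)
}

#' Associate the brain age gap with residualized brain volumes
#'
#' For each phenotype, fits ordinary least squares of the scaled residual on
#' the exposure (continuous gap z-score, or extreme-ager indicators with the
#' non-extreme group as reference), adjusting for the Model-3 covariate set
#' plus the baseline-to-scan interval and prevalent Parkinson's disease and
#' multiple sclerosis.
#'
#' @param residuals Output of [residualize_volumes()].
#' @param gaps A classified `gap_result` ([classify_agers()]).
#' @param cohort Covariate tibble (post-[prepare_covariates()]).
#' @param exposure "gap_z" or "ager_class".
#' @param volumes Optional volume tibble supplying `interval_years`.
#' @param min_n Refuse to fit with fewer joined participants.
#' @return Tibble: phenotype, term, beta, se, p_value, n.
#' @export
volume_association <- function(residuals, gaps, cohort,
                               exposure = c("gap_z", "ager_class"),
                               volumes = NULL, min_n = 50L) {
  exposure <- match.arg(exposure)
  covs <- intersect(c(covariate_tiers$M3, "parkinsons", "multiple_sclerosis"),
                    names(cohort))
  gap_cols <- intersect(c("participant", "gap_z", "ager_class"), names(gaps))
  dat <- residuals |>
    dplyr::inner_join(tibble::as_tibble(gaps)[gap_cols], by = "participant") |>
    dplyr::inner_join(cohort[unique(c("participant", covs))],
                      by = "participant")
  if (!is.null(volumes) && "interval_years" %in% names(volumes)) {
    dat <- dplyr::inner_join(dat,
                             volumes[c("participant", "interval_years")],
                             by = "participant")
    covs <- c(covs, "interval_years")
  }
  if (length(unique(dat$participant)) < min_n) {
    abort(sprintf("fewer than %d joined participants", min_n))
  }
  if (exposure == "ager_class") {
    dat$ager_class <- stats::relevel(factor(dat$ager_class),
                                     ref = "non_extreme")
  }
  rhs <- paste(c(exposure, covs), collapse = " + ")
  dat |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::group_modify(function(d, key) {
      fit <- lm(as.formula(paste("scaled_residual ~", rhs)), data = d)
      co <- summary(fit)$coefficients
      keep <- grep(paste0("^", exposure), rownames(co), value = TRUE)
      tibble::tibble(term = keep, beta = co[keep, "Estimate"],
                     se = co[keep, "Std. Error"],
                     p_value = co[keep, "Pr(>|t|)"], n = nrow(d))
    }) |>
    dplyr::ungroup()
}
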