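#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the restricted-cubic-spline hazard-ratio curve
#'
#' @param rcs A `rcs_result` from [rcs_nonlinearity()].
#' @return A ggplot: HR (log scale) with 95% band against gap z-score,
#'   reference line at HR = 1.
#' @export
plot_spline_hr <- function(rcs) {
  ggplot2::ggplot(rcs$curve, ggplot2::aes(x = .data$gap_z, y = .data$hr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Brain age gap (z-score)", y = "Hazard ratio",
                  subtitle = sprintf("P nonlinearity = %.3g", rcs$p_nonlinear))
}

#' @export
#' @method autoplot rcs_result
autoplot.rcs_result <- function(object, ...) plot_spline_hr(object)

#' Forest plot of association results
#'
#' @param results A tidy association tibble (rows from [fit_cox()],
#'   [sensitivity_suite()] or [subgroup_interactions()]`$strata`).
#' @param label Column used for the y axis (default `stratum`, falling back
#'   to `scenario` or `term`).
#' @return A ggplot of hazard ratios with 95% CIs on a log scale.
#' @export
plot_forest <- function(results, label = NULL) {
  label <- label %||% intersect(c("stratum", "scenario", "term"),
                                names(results))[1]
  results$.label <- dplyr::coalesce(as.character(results[[label]]),
                                    results$term)
  ggplot2::ggplot(results, ggplot2::aes(x = .data$hr, y = .data$.label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL)
}

#' Plot Schoenfeld residuals against time
#'
#' @param check Result of [schoenfeld_check()].
#' @return A ggplot of scaled residuals with a smooth trend.
#' @export
plot_schoenfeld <- function(check) {
  ggplot2::ggplot(check$residuals, ggplot2::aes(x = .data$time,
                                                y = .data$residual)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = TRUE,
                         colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Event time (years)", y = "Scaled Schoenfeld residual",
                  subtitle = sprintf("PH test P = %.3g", check$p))
}
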