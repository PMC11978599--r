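# Independent oracles, kept deliberately naive and separate from the package
# implementation paths they check.

# Tricube weighted least squares at a single evaluation point, computed from
# the normal equations (the package uses lm.wfit on a grid + interpolation).
oracle_loess_point <- function(x, y, x0, span = 2 / 3, degree = 1L) {
  n <- length(x)
  q <- ceiling(span * n)
  d <- abs(x - x0)
  dmax <- sort(d)[q]
  keep <- d <= dmax
  u <- d[keep] / dmax
  w <- ((1 - u^3)^3) * (u <= 1)
  keep2 <- w > 0
  xs <- x[keep][keep2] - x0
  ys <- y[keep][keep2]
  ws <- w[keep2]
  X <- outer(xs, 0:degree, `^`)
  A <- t(X) %*% (ws * X)
  b <- t(X) %*% (ws * ys)
  drop(solve(A, b))[1]
}

# Cox partial log-likelihood for untied event times, written out directly.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_mle <- function(time, event, x) {
  stats::optimize(function(b) oracle_cox_loglik(b, time, event, x),
                  interval = c(-20, 20), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Tiny survival fixtures (no ties, a single covariate, finite MLE: the
# exposed subject must not always fail first, or the likelihood is monotone).
toy_cox_fixtures <- function() {
  list(
    three = list(time = c(1, 2, 3), event = c(1, 1, 0), x = c(0, 1, 0)),
    five = list(time = c(0.5, 1.2, 2.1, 3.3, 4.0),
                event = c(1, 0, 1, 1, 0), x = c(0.2, -1, 1.5, 0, 0.7)),
    six = list(time = c(0.3, 0.9, 1.4, 2.2, 2.9, 3.6),
               event = c(1, 1, 0, 1, 1, 0), x = c(1, 1, 0, 0, 1, 0))
  )
}

# A toy fixture wrapped in the analysis-table layout used by fit_cox().
toy_cox_data <- function(fx) {
  tibble::tibble(participant = sprintf("T%02d", seq_along(fx$time)),
                 time = fx$time, event_all_cause = fx$event, gap_z = fx$x)
}

skewness <- function(x) mean(((x - mean(x)) / sd(x))^3)

# Analysis table with the ground-truth standardized offset as the exposure
# (the gap a noiseless clock would yield), for survival-stage tests that
# should not be diluted by clock measurement error.
truth_analysis_table <- function(sim) {
  g <- tibble::tibble(participant = sim$truth$delta$participant,
                      gap_z = sim$truth$delta$delta_z)
  g$ager_class <- factor(
    dplyr::case_when(g$gap_z < -2 ~ "extreme_young",
                     g$gap_z > 2 ~ "extreme_old",
                     TRUE ~ "non_extreme"),
    levels = c("extreme_young", "non_extreme", "extreme_old"))
  dplyr::inner_join(prepare_covariates(sim$cohort), g, by = "participant")
}
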