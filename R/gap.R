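#' Locally weighted regression (LOESS) of predicted age on chronological age
#'
#' Classic nearest-neighbour local polynomial regression: at each of
#' `grid_size` equally spaced evaluation points over the observed range, a
#' weighted least-squares polynomial of degree `degree` is fitted to the
#' `ceiling(span * n)` nearest observations with tricube weights
#' `w = (1 - (d/dmax)^3)^3`, and the fitted value at the point is retained.
#' Predictions at arbitrary ages interpolate linearly between grid points. No
#' robustness iterations are applied. Windows become asymmetric near the range
#' edges (standard nearest-neighbour behaviour).
#'
#' @param x,y Numeric vectors (chronological and predicted age).
#' @param span Fraction of points in each local fit, in (0, 1].
#' @param degree Local polynomial degree (1 = local linear).
#' @param grid_size Number of evaluation points.
#' @return Object of class `loess_curve` with the evaluation grid and fitted
#'   means; use `predict()` to evaluate at new ages.
#' @export
loess_fit <- function(x, y, span = 2 / 3, degree = 1L, grid_size = 512L) {
  if (length(x) != length(y)) abort("`x` and `y` must be equal length")
  n <- length(x)
  if (n < 20L) abort("need at least 20 points")
  if (sd(x) == 0) abort("`x` is constant")
  if (span <= 0 || span > 1) abort("`span` must be in (0, 1]")
  q <- ceiling(span * n)
  if (q < degree + 2L) abort("too few neighbours for the requested degree")
  grid <- seq(min(x), max(x), length.out = grid_size)
  fitted <- vapply(grid, function(x0) {
    d <- abs(x - x0)
    dmax <- sort(d, partial = q)[q]
    if (dmax == 0) return(mean(y[d == 0]))
    in_win <- d <= dmax
    w <- tricube(d[in_win] / dmax)
    xw <- x[in_win] - x0
    # weights at the window edge are exactly 0; guard the fit
    pos <- w > 0
    X <- outer(xw[pos], 0:degree, `^`)
    fit <- lm.wfit(X, y[in_win][pos], w[pos])
    fit$coefficients[1]
  }, numeric(1))
  structure(list(grid = grid, fitted = fitted, span = span,
                 degree = as.integer(degree), range = range(x), n = n),
            class = "loess_curve")
}

#' Evaluate a fitted LOESS curve
#'
#' @param object A `loess_curve`.
#' @param newx Ages at which to evaluate (clamped to the fitted range).
#' @param ... Unused.
#' @return Numeric vector of population-mean predicted ages.
#' @export
predict.loess_curve <- function(object, newx, ...) {
  approx(object$grid, object$fitted, xout = pmin(pmax(newx, object$range[1]),
                                                 object$range[2]))$y
}

#' @export
#' @method tidy loess_curve
tidy.loess_curve <- function(x, ...) {
  tibble::tibble(age = x$grid, population_mean = x$fitted)
}

#' Brain age gap: LOESS-detrended, z-standardized predicted-age residual
#'
#' The gap is the difference between the predicted brain age and the LOESS
#' population-mean predicted age at the same chronological age; it is then
#' z-standardized over the cohort. Detrending against the fitted mean (rather
#' than chronological age itself) removes the regression-to-the-mean bias of
#' age clocks, leaving a gap essentially uncorrelated with chronological age.
#'
#' @param data Tibble with participant ids, predicted and chronological ages.
#' @param curve Optional pre-fitted [loess_fit()] curve; fitted internally
#'   from `data` when `NULL`.
#' @param predicted,age,id Column names in `data`.
#' @param span,degree Passed to [loess_fit()] when `curve` is `NULL`.
#' @return Tibble of class `gap_result`: participant, chron_age,
#'   predicted_age, population_mean, gap (years), gap_z; the fitted curve is
#'   kept in the `"curve"` attribute.
#' @export
compute_gap <- function(data, curve = NULL, predicted = "predicted_age",
                        age = "age", id = "participant", span = 2 / 3,
                        degree = 1L) {
  chron <- data[[age]]
  pred <- data[[predicted]]
  if (is.null(chron) || is.null(pred)) abort("missing predicted/age columns")
  if (is.null(curve)) curve <- loess_fit(chron, pred, span = span,
                                         degree = degree)
  pop_mean <- predict(curve, chron)
  gap <- pred - pop_mean
  if (sd(gap) < 1e-12) abort("degenerate cohort: gap has zero variance")
  out <- tibble::tibble(
    participant = if (!is.null(data[[id]])) data[[id]]
                  else as.character(seq_along(chron)),
    chron_age = chron, predicted_age = pred, population_mean = pop_mean,
    gap = gap, gap_z = (gap - mean(gap)) / sd(gap)
  )
  attr(out, "curve") <- curve
  class(out) <- c("gap_result", class(out))
  out
}

#' Classify extreme agers and quartiles of the non-extremes
#'
#' Participants with gap z-score strictly below -2 are extreme young agers and
#' strictly above 2 extreme old agers (boundary values count as non-extreme).
#' Non-extreme participants are ranked by gap z-score (ties broken by
#' participant id) and split into four groups as equal as possible: group
#' sizes differ by at most one, with the lower quartiles taking any remainder.
#'
#' @param gaps A `gap_result` from [compute_gap()].
#' @return The input with `ager_class` (factor: extreme_young, non_extreme,
#'   extreme_old) and `quartile` (integer 1-4, `NA` for extremes) added.
#' @export
classify_agers <- function(gaps) {
  stopifnot(all(c("gap_z", "participant") %in% names(gaps)))
  gaps$ager_class <- factor(
    dplyr::case_when(gaps$gap_z < -2 ~ "extreme_young",
                     gaps$gap_z > 2 ~ "extreme_old",
                     TRUE ~ "non_extreme"),
    levels = c("extreme_young", "non_extreme", "extreme_old"))
  gaps$quartile <- NA_integer_
  ne <- which(gaps$ager_class == "non_extreme")
  ord <- ne[order(gaps$gap_z[ne], gaps$participant[ne])]
  m <- length(ord)
  base <- m %/% 4L
  sizes <- base + as.integer(seq_len(4L) <= m %% 4L)
  gaps$quartile[ord] <- rep(1:4, times = sizes)
  gaps
}

#' Check that the gap is decorrelated from chronological age
#'
#' @param gaps A `gap_result`.
#' @param threshold Maximum tolerated absolute Pearson correlation.
#' @return Tibble: pearson_r, abs_r, threshold, pass.
#' @export
decorrelation_check <- function(gaps, threshold = 0.001) {
  if (nrow(gaps) < 100L) abort("need at least 100 participants")
  if (sd(gaps$chron_age) == 0) abort("chronological age is constant")
  r <- cor(gaps$gap_z, gaps$chron_age)
  tibble::tibble(pearson_r = r, abs_r = abs(r), threshold = threshold,
                 pass = abs(r) <= threshold)
}

#' @export
#' @method autoplot gap_result
autoplot.gap_result <- function(object, ...) {
  curve <- attr(object, "curve")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$chron_age,
                                            y = .data$predicted_age)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(x = "Chronological age (years)",
                  y = "Predicted brain age (years)")
  if (!is.null(curve)) {
    p <- p + ggplot2::geom_line(data = tidy(curve),
                                ggplot2::aes(x = .data$age,
                                             y = .data$population_mean),
                                colour = "firebrick", linewidth = 0.8)
  }
  p
}
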