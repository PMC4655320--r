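#' Fit a gestational-age-adjusted Z-score model
#'
#' Ultrasound scans happen at slightly different gestational ages, so raw
#' biometry is not comparable across a cohort. This fits, within the cohort,
#' a polynomial mean curve of the measurement on GA by least squares, and an
#' SD curve by least-squares regression of the absolute residuals on the same
#' polynomial basis scaled by `sqrt(pi/2)` (the absolute-moment factor for a
#' normal residual). Z-scores are `(value - mean(ga)) / sd(ga)`.
#'
#' @param ga_weeks decimal gestational ages.
#' @param value measurements (one measure per model).
#' @param degree polynomial degree for both curves (default 2).
#' @param min_n minimum number of observations required.
#' @return an object of class `zscore_model` with coefficient vectors
#'   `mean_coef` and `sd_coef`, the fitted `ga_range`, `degree` and `n`.
#' @export
fit_zscore_model <- function(ga_weeks, value, degree = 2, min_n = 100) {
  ok <- is.finite(ga_weeks) & is.finite(value)
  ga <- ga_weeks[ok]; y <- value[ok]
  if (length(y) < min_n)
    stop_gs("need at least %d observations to fit a Z-score model (have %d)",
            min_n, length(y), class = "gs_fit_error")
  if (diff(range(ga)) < 2)
    stop_gs("gestational ages span %.2f weeks; need at least 2 for a stable fit",
            diff(range(ga)), class = "gs_fit_error")
  X <- stats::poly(ga, degree, raw = TRUE)
  fit_mean <- stats::lm.fit(cbind(1, X), y)
  res <- fit_mean$residuals
  fit_sd <- stats::lm.fit(cbind(1, X), abs(res))
  m <- structure(list(mean_coef = unname(fit_mean$coefficients),
                      sd_coef = unname(fit_sd$coefficients) * sqrt(pi / 2),
                      degree = degree, ga_range = range(ga), n = length(y)),
                 class = "zscore_model")
  grid <- seq(m$ga_range[1], m$ga_range[2], length.out = 101)
  if (any(zmodel_sd(m, grid) <= 0))
    stop_gs("fitted SD curve is not strictly positive on the GA range",
            class = "gs_fit_error")
  m
}

zmodel_basis <- function(model, ga) {
  outer(ga, 0:model$degree, `^`)
}

zmodel_mean <- function(model, ga) drop(zmodel_basis(model, ga) %*% model$mean_coef)
zmodel_sd <- function(model, ga) drop(zmodel_basis(model, ga) %*% model$sd_coef)

#' Gestational-age-adjusted Z-score
#'
#' @param model a fitted [fit_zscore_model()] object.
#' @param ga_weeks decimal gestational ages.
#' @param value measurements.
#' @return Z-scores.
#' @export
zscore <- function(model, ga_weeks, value) {
  stopifnot(inherits(model, "zscore_model"))
  (value - zmodel_mean(model, ga_weeks)) / zmodel_sd(model, ga_weeks)
}

#' Abdominal-circumference growth velocity
#'
#' The change in the GA-adjusted AC Z-score between the 20-week scan and the
#' last scan before birth. Negative values indicate decelerating abdominal
#' growth relative to the cohort.
#'
#' @param z_20wk AC Z-score at the 20-week scan.
#' @param z_last AC Z-score at the last scan before birth.
#' @return `z_last - z_20wk`.
#' @export
ac_growth_velocity <- function(z_20wk, z_last) {
  if (anyNA(z_20wk) || anyNA(z_last) || !all(is.finite(c(z_20wk, z_last))))
    stop_gs("growth velocity needs finite Z-scores at both the 20-week and the last scan",
            class = "gs_missing_input")
  z_last - z_20wk
}
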