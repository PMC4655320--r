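#' Round half away from zero
#'
#' Report tables round percentages to integers and ratios to one decimal with
#' ties going up (5 rounds away from zero), matching common clinical-table
#' convention rather than R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return a list with `est`, `lower`, `upper` (proportions in \[0, 1\]).
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(est = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

# Wald interval, used only when logging which CI method matches a printed value
wald_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  half <- z * sqrt(p * (1 - p) / n)
  list(est = p, lower = max(0, p - half), upper = min(1, p + half))
}

mm_to_cm <- function(x) x / 10
cm_to_mm <- function(x) x * 10

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gs <- function(fmt, ..., class) {
  rlang::abort(sprintf(fmt, ...), class = c(class, "growthscreen_error"))
}
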