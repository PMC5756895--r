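#' Temperature-dependent median development-rate curve
#'
#' Two functional families are provided:
#'
#' * `"linear_degree_day"`: the classic degree-day model,
#'   `r(T) = max(0, slope * (T - base_temp))`. Parameters: `base_temp`
#'   (degC), `slope` (day^-1 degC^-1).
#' * `"hump_nonlinear"`: a Logan-type single-peaked curve,
#'   `r(T) = psi * (exp(rho*(T - t_base)) - exp(rho*(t_max - t_base) - (t_max - T)/delta))`
#'   for `t_base < T < t_max` and 0 outside, clamped at 0. Parameters:
#'   `psi` (scale, day^-1), `rho` (exponential shape, degC^-1), `t_base`
#'   (lower threshold, degC), `t_max` (upper lethal threshold, degC),
#'   `delta` (width of the high-temperature decline, degC). Rates rise
#'   roughly exponentially from the base, peak below `t_max`, and collapse
#'   to zero at the upper threshold.
#'
#' Rates at or below `clip_floor` (default 1e-8 day^-1) are treated as
#' exactly zero development: the log-normal location parameter `ln(r dt)`
#' is undefined at zero rate, and biologically development halts in cold.
#'
#' @param family `"linear_degree_day"` or `"hump_nonlinear"`.
#' @param ... named curve parameters (see above).
#' @param clip_floor minimum admissible rate (day^-1, >= 0).
#' @return An object of class `"rate_curve"`.
#' @export
rate_curve <- function(family = c("linear_degree_day", "hump_nonlinear"),
                       ..., clip_floor = 1e-8) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
                 linear_degree_day = c("base_temp", "slope"),
                 hump_nonlinear = c("psi", "rho", "t_base", "t_max", "delta"))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("missing ", family, " parameter(s): ", paste(missing, collapse = ", "))
  stopifnot(clip_floor >= 0)
  if (family == "hump_nonlinear" && params$t_max <= params$t_base)
    stop("t_max must exceed t_base")
  structure(list(family = family, params = params, clip_floor = clip_floor),
            class = "rate_curve")
}

#' Median development rate at a temperature
#'
#' Evaluates the median (population-level) development rate of a
#' [rate_curve()]. Vectorized over `temp`. Always finite and nonnegative.
#'
#' @param curve a [rate_curve()].
#' @param temp temperature(s), degC.
#' @return Rate(s) in day^-1.
#' @export
median_rate <- function(curve, temp) {
  stopifnot(inherits(curve, "rate_curve"), all(is.finite(temp)))
  p <- curve$params
  r <- switch(curve$family,
    linear_degree_day = pmax(0, p$slope * (temp - p$base_temp)),
    hump_nonlinear = {
      tau_m <- p$t_max - p$t_base
      v <- p$psi * (exp(p$rho * (temp - p$t_base)) -
                    exp(p$rho * tau_m - (p$t_max - temp) / p$delta))
      v[temp <= p$t_base | temp >= p$t_max] <- 0
      pmax(0, v)
    })
  r
}

#' Temperature of maximum development rate
#'
#' Numerically locates the thermal optimum of a rate curve (useful for
#' checking a hump-shaped parameterization).
#'
#' @param curve a [rate_curve()].
#' @param lower,upper search interval (degC); defaults cover the curve's
#'   support for the hump family.
#' @return Temperature of the rate maximum, degC.
#' @export
rate_curve_optimum <- function(curve, lower = NULL, upper = NULL) {
  stopifnot(inherits(curve, "rate_curve"))
  if (curve$family == "hump_nonlinear") {
    lower <- lower %||% curve$params$t_base
    upper <- upper %||% curve$params$t_max
  } else {
    lower <- lower %||% -10
    upper <- upper %||% 50
  }
  stats::optimize(function(t) median_rate(curve, t),
                  interval = c(lower, upper), maximum = TRUE)$maximum
}

#' Rate summation: cumulative physiological age
#'
#' Riemann-sum accumulation of development over a temperature record:
#' `a(t_n) = sum_i r[T(t_i)] * dt`. The returned series starts at the first
#' increment and is nondecreasing.
#'
#' @param curve a [rate_curve()].
#' @param temps temperature sequence (degC), one per step.
#' @param dt step length in days.
#' @return Numeric vector of cumulative physiological age, same length as
#'   `temps`.
#' @export
rate_summation <- function(curve, temps, dt = 1) {
  if (length(temps) == 0L) stop("temps must be nonempty")
  r <- median_rate(curve, temps)
  r[r <= curve$clip_floor] <- 0
  cumsum(r * dt)
}

#' Log-normal development-rate variability specification
#'
#' Pairs a median rate curve with the stage-specific log-normal scale
#' parameter `sigma`. Per-step aging increments are distributed
#' `LN(mu = ln(r[T] dt), sigma^2)`, so the increment median is exactly
#' `r[T] dt` and `sigma = 0` is the deterministic limit.
#'
#' @param curve a [rate_curve()].
#' @param sigma log-normal scale parameter (dimensionless, >= 0).
#' @return An object of class `"lognormal_rate_spec"`.
#' @export
lognormal_rate_spec <- function(curve, sigma) {
  stopifnot(inherits(curve, "rate_curve"), sigma >= 0)
  structure(list(curve = curve, sigma = sigma),
            class = "lognormal_rate_spec")
}

#' Log-normal increment parameters at a temperature
#'
#' Computes the location and scale of the per-step aging-increment
#' distribution: `mu = ln(median_rate * dt)`, `sigma` from the spec. When
#' the median rate is at or below the curve's `clip_floor` the increment is
#' degenerate at zero (no development); this is signalled through
#' `degenerate = TRUE` rather than an error so callers can branch to the
#' identity kernel.
#'
#' @param spec a [lognormal_rate_spec()].
#' @param temp temperature, degC.
#' @param dt step length, days.
#' @return List with `mu`, `sigma`, `median` (= `r dt`), and `degenerate`.
#' @export
lognormal_increment_params <- function(spec, temp, dt = 1) {
  stopifnot(inherits(spec, "lognormal_rate_spec"))
  r <- median_rate(spec$curve, temp)
  if (r <= spec$curve$clip_floor)
    return(list(mu = -Inf, sigma = spec$sigma, median = 0, degenerate = TRUE))
  list(mu = log(r * dt), sigma = spec$sigma, median = r * dt,
       degenerate = FALSE)
}
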