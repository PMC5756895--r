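#' Stage mortality rule
#'
#' Either no mortality or the cold-snap step function used for the
#' cold-sensitive mountain pine beetle stages: the daily probability of
#' death is 1 when the minimum temperature drops strictly below the
#' threshold (default -18 degC) and 0 otherwise. A day at exactly the
#' threshold kills nothing (the boundary follows the "below" wording of
#' the underlying field rule).
#'
#' @param kind `"none"` or `"cold_step"`.
#' @param threshold lethal minimum temperature, degC.
#' @return An object of class `"mortality_rule"`.
#' @export
mortality_rule <- function(kind = c("none", "cold_step"), threshold = -18) {
  kind <- match.arg(kind)
  structure(list(kind = kind, threshold = threshold),
            class = "mortality_rule")
}

#' Daily mortality probability from a rule
#'
#' @param rule a [mortality_rule()].
#' @param tmin daily minimum temperature, degC.
#' @return Probability in `[0, 1]`; the cold-step rule returns only 0 or 1.
#' @export
mortality_prob <- function(rule, tmin) {
  stopifnot(inherits(rule, "mortality_rule"))
  switch(rule$kind,
         none = 0,
         cold_step = as.numeric(tmin < rule$threshold))
}

#' Adult flight model
#'
#' Emerged adults take flight on days whose maximum temperature strictly
#' exceeds the flight threshold (default 18.3 degC, an observed beetle
#' flight threshold). Flying beetles settle (cease flight) by exponential
#' decay of the flying pool: a fraction `1 - exp(-settling_rate * dt)`
#' settles per day. The settling rate is a required configuration
#' parameter; the default corresponds to a flight half-life of 3 days and
#' is illustrative, not a fitted value. Emerged, flying, and settled pools
#' sit outside the staged populations and are not subject to the cold-step
#' rule.
#'
#' @param flight_threshold degC; flight on days with `tmax` strictly above.
#' @param settling_rate exponential settling rate, day^-1 (> 0).
#' @return An object of class `"flight_model"`.
#' @export
flight_model <- function(flight_threshold = 18.3,
                         settling_rate = log(2) / 3) {
  stopifnot(settling_rate > 0)
  structure(list(flight_threshold = flight_threshold,
                 settling_rate = settling_rate),
            class = "flight_model")
}

#' Advance the adult flight pools one day
#'
#' Settling acts first on the beetles already aloft, then the day's
#' emerged pool takes flight if the maximum temperature allows (new flyers
#' begin settling the next day). All mass is conserved across the three
#' pools.
#'
#' @param emerged_pool mass of emerged, not-yet-flying adults (>= 0).
#' @param flying_pool mass currently aloft (>= 0).
#' @param tmax daily maximum temperature, degC.
#' @param model a [flight_model()].
#' @param dt step length, days.
#' @return List with updated `emerged`, `flying`, `newly_settled`, and
#'   `newly_flying`.
#' @export
flight_step <- function(emerged_pool, flying_pool, tmax, model, dt = 1) {
  stopifnot(inherits(model, "flight_model"),
            emerged_pool >= 0, flying_pool >= 0)
  settled <- flying_pool * (1 - exp(-model$settling_rate * dt))
  flying <- flying_pool - settled
  newly_flying <- 0
  if (tmax > model$flight_threshold) {
    newly_flying <- emerged_pool
    flying <- flying + newly_flying
    emerged_pool <- 0
  }
  list(emerged = emerged_pool, flying = flying,
       newly_settled = settled, newly_flying = newly_flying)
}

#' Egg-introduction schedule from a start-time distribution
#'
#' Distributes a brood over introduction dates proportionally to supplied
#' weights — typically the previous year's normalized trap-catch curve, so
#' the simulated generation starts when its parents actually flew. Each
#' introduction enters the egg stage at age zero on its date.
#'
#' @param dates introduction dates.
#' @param weights nonnegative relative weights, at least one positive.
#' @param egg_count total egg mass to distribute (default 82, one brood).
#' @return Data frame with columns `date` and `mass` (summing to
#'   `egg_count`), suitable for `simulate_ipm(introductions = )`.
#' @export
initialize_from_start_times <- function(dates, weights, egg_count = 82) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(weights), egg_count >= 0)
  if (any(weights < 0)) stop("weights must be nonnegative")
  tot <- sum(weights)
  if (tot <= 0) stop("all start-time weights are zero")
  data.frame(date = dates, mass = egg_count * weights / tot)
}

#' The eight-stage mountain pine beetle life cycle
#'
#' Builds the ordered stage list: egg, four larval instars (L1-L4), pupa,
#' teneral adult, and adult, each with a Logan-type hump-shaped median
#' rate curve, a log-normal rate-variability scale, and a maturation
#' threshold of 1. The cold-step mortality rule (-18 degC) is wired to the
#' cold-sensitive stages (egg, pupa, teneral adult, adult); the larval
#' instars, which cold-harden, carry no mortality rule.
#'
#' Stage parameters are read from a YAML file (see
#' `system.file("extdata", "mpb_life_cycle.yaml", package = "phenoipm")`
#' for the format). The bundled values are illustrative: they give
#' field-realistic stage durations (egg about 10 days at 20 degC, the
#' fourth instar the slowest, a one-year life cycle under montane forcing)
#' but are not fitted to rearing data.
#'
#' @param config_path YAML life-cycle configuration; default the bundled
#'   file.
#' @return List with `stages` (list of [stage_spec()]s) and `flight`
#'   (a [flight_model()]).
#' @export
mpb_life_cycle <- function(config_path = NULL) {
  path <- config_path %||%
    system.file("extdata", "mpb_life_cycle.yaml", package = "phenoipm")
  cfg <- yaml::read_yaml(path)
  stages <- lapply(cfg$stages, function(st) {
    curve <- do.call(rate_curve, c(list(family = st$family), st$params,
                                   list(clip_floor = st$clip_floor %||% 1e-8)))
    stage_spec(name = st$name,
               rate_spec = lognormal_rate_spec(curve, st$sigma),
               gamma = st$gamma %||% 1,
               mortality = mortality_rule(st$mortality %||% "none",
                                          threshold = cfg$cold_threshold %||% -18))
  })
  fl <- flight_model(flight_threshold = cfg$flight$flight_threshold %||% 18.3,
                     settling_rate = cfg$flight$settling_rate %||% log(2) / 3)
  list(stages = stages, flight = fl)
}

#' Reference synthetic forcing year for the beetle life cycle
#'
#' One full life cycle (443 days from mid-July) of synthetic montane
#' forcing generated with the package defaults; see
#' [synthetic_forcing_config()].
#'
#' @param seed RNG seed for the forcing noise.
#' @return A [temperature_series()].
#' @export
mpb_reference_forcing <- function(seed = 1L) {
  generate_synthetic_series(synthetic_forcing_config(seed = seed))
}

#' Read a flight trap-catch CSV
#'
#' Expects columns `date` and `count` (trapped beetles per record date).
#'
#' @param path CSV file path.
#' @return Data frame of class `"trap_series"` with columns `date`,
#'   `count`, and `normalized_cumulative`.
#' @export
read_trap_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("date", "count") %in% names(raw)))
    stop("trap CSV needs 'date' and 'count' columns")
  trap_series(raw$date, raw$count)
}

#' Trap-catch series
#'
#' @param dates record dates.
#' @param counts trapped beetles per record (>= 0).
#' @return Data frame of class `"trap_series"` ordered by date, with the
#'   normalized cumulative catch (ending at 1 when any beetle was caught).
#' @export
trap_series <- function(dates, counts) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(counts))
  if (any(counts < 0)) stop("trap counts must be nonnegative")
  o <- order(dates)
  dates <- dates[o]
  counts <- as.numeric(counts[o])
  tot <- sum(counts)
  nc <- if (tot > 0) cumsum(counts) / tot else rep(0, length(counts))
  out <- data.frame(date = dates, count = counts,
                    normalized_cumulative = nc)
  class(out) <- c("trap_series", "data.frame")
  out
}

#' Normalized cumulative flight curve of a simulation
#'
#' Cumulative newly-flying mass divided by the total mass that ever flew:
#' a nondecreasing curve on `[0, 1]` reaching exactly 1 whenever any
#' flight occurred, directly comparable to a normalized cumulative trap
#' catch. If the run produced no flight the curve is flagged empty rather
#' than dividing by zero.
#'
#' @param trajectory a `"phenology_trajectory"` simulated with a flight
#'   model.
#' @return Data frame with columns `date` and `cumulative_fraction`, plus
#'   attribute `empty` (`TRUE` when no flight occurred, in which case the
#'   fractions are all zero).
#' @export
cumulative_flight_curve <- function(trajectory) {
  stopifnot(inherits(trajectory, "phenology_trajectory"))
  nf <- trajectory$newly_flown
  tot <- sum(nf)
  empty <- tot <= 0
  frac <- if (empty) rep(0, length(nf)) else cumsum(nf) / tot
  out <- data.frame(date = trajectory$dates, cumulative_fraction = frac)
  attr(out, "empty") <- empty
  out
}
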