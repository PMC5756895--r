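#' Paired empirical cumulative distributions on a shared support
#'
#' Aligns an observed and a predicted flight-time distribution on the
#' union of their dates (or any ordered numeric support) and records the
#' effective sample sizes used for the Kolmogorov-Smirnov p-value.
#'
#' Two sample-size conventions are supported for count data. Counts are
#' always treated as frequency weights when forming the ECDFs (each
#' trapped beetle is one sample); the reported `n` is either the number of
#' records in the time series (`convention = "records"`, the convention
#' used when quoting trap-validation sample sizes) or the total count
#' (`convention = "counts"`).
#'
#' @param obs_times,pred_times observed / predicted support points (dates
#'   or numerics).
#' @param obs_weights,pred_weights nonnegative frequency weights (default
#'   1 per point).
#' @param convention `"records"` or `"counts"`.
#' @return An object of class `"ecdf_pair"` with the union `support`,
#'   nondecreasing `F_obs` and `F_pred` ending at 1, and `n_obs`, `n_pred`.
#' @export
ecdf_pair <- function(obs_times, pred_times,
                      obs_weights = NULL, pred_weights = NULL,
                      convention = c("records", "counts")) {
  convention <- match.arg(convention)
  obs_times <- as.numeric(obs_times)
  pred_times <- as.numeric(pred_times)
  obs_weights <- obs_weights %||% rep(1, length(obs_times))
  pred_weights <- pred_weights %||% rep(1, length(pred_times))
  stopifnot(length(obs_weights) == length(obs_times),
            length(pred_weights) == length(pred_times),
            all(obs_weights >= 0), all(pred_weights >= 0))
  if (length(obs_times) == 0L || length(pred_times) == 0L)
    stop("both samples must contain at least one record")
  if (sum(obs_weights) <= 0 || sum(pred_weights) <= 0)
    stop("both samples must carry positive total weight")
  support <- sort(unique(c(obs_times, pred_times)))
  wcdf <- function(times, w) {
    o <- order(times)
    cw <- cumsum(w[o]) / sum(w)
    idx <- findInterval(support, times[o])  # last sorted index <= support
    c(0, cw)[idx + 1L]
  }
  n_of <- function(times, w) {
    if (convention == "records") length(times) else sum(w)
  }
  structure(list(support = support,
                 F_obs = wcdf(obs_times, obs_weights),
                 F_pred = wcdf(pred_times, pred_weights),
                 n_obs = n_of(obs_times, obs_weights),
                 n_pred = n_of(pred_times, pred_weights),
                 convention = convention),
            class = "ecdf_pair")
}

#' Build an ECDF pair from a trap series and a simulated flight curve
#'
#' Convenience wrapper: the observed distribution comes from trap counts
#' (counts as frequency weights), the predicted one from the daily
#' newly-flying mass of a simulation.
#'
#' @param trap a [trap_series()].
#' @param trajectory a `"phenology_trajectory"` simulated with a flight
#'   model.
#' @param convention passed to [ecdf_pair()].
#' @return An `"ecdf_pair"`.
#' @export
flight_ecdf_pair <- function(trap, trajectory,
                             convention = c("records", "counts")) {
  stopifnot(inherits(trap, "trap_series"),
            inherits(trajectory, "phenology_trajectory"))
  keep <- trajectory$newly_flown > 0
  if (!any(keep)) stop("simulation produced no flight")
  ecdf_pair(trap$date, trajectory$dates[keep],
            obs_weights = trap$count,
            pred_weights = trajectory$newly_flown[keep],
            convention = match.arg(convention))
}

# Asymptotic Kolmogorov distribution tail: Q(lambda) = 2 sum (-1)^{k-1}
# exp(-2 k^2 lambda^2). Converges fast for lambda > ~0.3; below that the
# tail is indistinguishable from 1.
kolmogorov_tail <- function(lambda) {
  if (lambda < 1e-3) return(1)
  k <- seq_len(101L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test on an ECDF pair
#'
#' `D` is the maximum absolute difference between the two cumulative
#' curves over the union support; the p-value comes from the asymptotic
#' Kolmogorov distribution with effective sample size
#' `n = n_obs * n_pred / (n_obs + n_pred)`. Failure to reject the null
#' (both samples similarly distributed) is a positive validation result
#' for a phenology prediction.
#'
#' @param pair an [ecdf_pair()].
#' @return List with `D` (in `[0, 1]`), `p` (in `(0, 1]`), `n_obs`,
#'   `n_pred`.
#' @export
ks_two_sample <- function(pair) {
  stopifnot(inherits(pair, "ecdf_pair"))
  if (length(pair$support) == 0L) stop("empty ECDF pair")
  D <- max(abs(pair$F_obs - pair$F_pred))
  n_eff <- pair$n_obs * pair$n_pred / (pair$n_obs + pair$n_pred)
  p <- kolmogorov_tail(sqrt(n_eff) * D)
  list(D = D, p = max(p, .Machine$double.xmin),
       n_obs = pair$n_obs, n_pred = pair$n_pred)
}

#' Discrepancy between two simulated trajectories
#'
#' Per-stage maximum-absolute and integrated-absolute (sum x dt)
#' differences of the daily stage totals of two trajectories on matching
#' dates. Symmetric, and zero exactly when the trajectories agree.
#'
#' @param a,b `"phenology_trajectory"` objects with identical dates and
#'   stage sets.
#' @param dt step length in days used for the integrated difference.
#' @return Data frame with columns `stage`, `max_abs`, `int_abs`.
#' @export
trajectory_discrepancy <- function(a, b, dt = 1) {
  stopifnot(inherits(a, "phenology_trajectory"),
            inherits(b, "phenology_trajectory"))
  if (!identical(a$stage_names, b$stage_names))
    stop("trajectories have different stage sets")
  if (length(a$dates) != length(b$dates) || !all(a$dates == b$dates))
    stop("trajectories cover different dates")
  d <- abs(a$totals - b$totals)
  data.frame(stage = a$stage_names,
             max_abs = apply(d, 2L, max),
             int_abs = colSums(d) * dt,
             row.names = NULL)
}
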