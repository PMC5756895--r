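#' Draw stochastic aging increments
#'
#' One log-normal draw per individual from
#' `LN(mu = ln(r[T] dt), sigma^2)` — the stochastic rate-summation
#' increment whose density the projection kernel discretizes. Increments
#' are exactly zero when the median rate is at or below the curve's clip
#' floor (development halted by cold), and exactly `r dt` in the
#' deterministic limit `sigma = 0`.
#'
#' @param spec a [lognormal_rate_spec()].
#' @param temp temperature, degC (daily mean channel).
#' @param dt step length, days.
#' @param n number of draws.
#' @return Numeric vector of `n` nonnegative age increments.
#' @export
draw_increment <- function(spec, temp, dt = 1, n = 1L) {
  p <- lognormal_increment_params(spec, temp, dt)
  if (p$degenerate) return(numeric(n))
  if (p$sigma == 0) return(rep(p$median, n))
  stats::rlnorm(n, meanlog = p$mu, sdlog = p$sigma)
}

#' Individual-based model configuration
#'
#' @param n_individuals brood size; the default 82 is the egg complement of
#'   a single simulated mated female.
#' @param seed master RNG seed; per-replicate child seeds are derived from
#'   it deterministically, so the whole run is bit-reproducible while
#'   replicates stay independent.
#' @param n_replicates number of independent stochastic replicates.
#' @return A list of class `"ibm_config"`.
#' @export
ibm_config <- function(n_individuals = 82L, seed = 1L, n_replicates = 20L) {
  stopifnot(n_individuals >= 1L, n_replicates >= 1L)
  structure(list(n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "ibm_config")
}

# Population is a list of parallel vectors: stage (1-based; n_stages + 1
# means matured out of the final stage, i.e. emerged), age within stage,
# alive flag. Dead individuals never change state again.
new_ibm_population <- function(n) {
  list(stage = rep(1L, n), age = numeric(n), alive = rep(TRUE, n))
}

#' Advance the individual-based model one step
#'
#' Per living individual: add a fresh log-normal increment for its current
#' stage (fresh draw each step — increments are step-independent), apply
#' the current stage's mortality from the day's minimum temperature, then
#' mature into the next stage if accrued development has reached the
#' stage's threshold. On maturation the excess above the threshold is
#' discarded: individuals enter the next stage at age exactly zero,
#' matching the projection model's point-mass recruitment. Individuals that
#' complete the final stage move to the emerged pool
#' (`stage = n_stages + 1`).
#'
#' @param pop population list as returned by this function (fields `stage`,
#'   `age`, `alive`).
#' @param temps_today list or one-row data frame with `tmin` and `tmean`.
#' @param stages ordered list of [stage_spec()]s.
#' @param dt step length, days.
#' @return The updated population list.
#' @export
step_ibm <- function(pop, temps_today, stages, dt = 1) {
  tmin <- temps_today[["tmin"]]
  tmean <- temps_today[["tmean"]]
  n_s <- length(stages)
  stage0 <- pop$stage  # membership frozen at step start: one draw each
  for (s in seq_len(n_s)) {
    idx <- which(pop$alive & stage0 == s)
    if (!length(idx)) next
    sp <- stages[[s]]
    pop$age[idx] <- pop$age[idx] +
      draw_increment(sp$rate_spec, tmean, dt, n = length(idx))
    m <- mortality_prob(sp$mortality, tmin)
    if (m > 0) {
      killed <- idx[stats::runif(length(idx)) < m]
      pop$alive[killed] <- FALSE
    }
    live <- idx[pop$alive[idx]]
    up <- live[pop$age[live] >= sp$gamma - 1e-12]
    if (length(up)) {
      pop$stage[up] <- s + 1L
      pop$age[up] <- 0
    }
  }
  pop
}

#' Simulate the stochastic individual-based model
#'
#' Runs `n_replicates` independent stochastic simulations of the brood over
#' the forcing series and tabulates daily occupancy of each stage plus the
#' emerged pool. This is the stochastic process that the integral
#' projection model represents deterministically: its across-replicate
#' mean trajectories converge on the projection model's stage totals.
#'
#' @param series a [temperature_series()].
#' @param stages ordered list of [stage_spec()]s.
#' @param cfg an [ibm_config()].
#' @param dt step length in days; defaults to the series' `step_days`.
#' @return An object of class `"ibm_trajectories"`: `counts`, an array of
#'   dimension `(replicate, day, stage)` (last stage slot is `emerged`;
#'   a final `dead` slot closes the ledger), plus `mean` and `se` matrices
#'   (day x stage) across replicates.
#' @export
simulate_ibm <- function(series, stages, cfg = ibm_config(), dt = NULL) {
  stopifnot(inherits(series, "temperature_series"))
  dt <- dt %||% attr(series, "step_days") %||% 1
  n_days <- nrow(series)
  n_s <- length(stages)
  labels <- c(vapply(stages, function(s) s$name, ""), "emerged", "dead")
  child_seeds <- with_seed(cfg$seed,
                           sample.int(.Machine$integer.max, cfg$n_replicates))
  counts <- array(0L, dim = c(cfg$n_replicates, n_days, n_s + 2L),
                  dimnames = list(NULL, NULL, labels))
  for (rep_i in seq_len(cfg$n_replicates)) {
    counts[rep_i, , ] <- with_seed(child_seeds[rep_i], {
      pop <- new_ibm_population(cfg$n_individuals)
      out <- matrix(0L, n_days, n_s + 2L)
      for (i in seq_len(n_days)) {
        pop <- step_ibm(pop, series[i, ], stages, dt)
        out[i, seq_len(n_s + 1L)] <- tabulate(pop$stage[pop$alive],
                                              nbins = n_s + 1L)
        out[i, n_s + 2L] <- sum(!pop$alive)
      }
      out
    })
  }
  mn <- apply(counts, c(2L, 3L), mean)
  se <- apply(counts, c(2L, 3L), stats::sd) / sqrt(cfg$n_replicates)
  colnames(mn) <- colnames(se) <- labels
  structure(list(counts = counts, mean = mn, se = se,
                 dates = series$date, stage_names = labels, cfg = cfg),
            class = "ibm_trajectories")
}

#' Write individual-based replicate trajectories to CSV
#'
#' Long format: replicate, date, stage, count. A companion summary file
#' (`*_summary.csv`) holds the across-replicate mean and standard error.
#'
#' @param ibm an `"ibm_trajectories"` object from [simulate_ibm()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ibm_csv <- function(ibm, path) {
  stopifnot(inherits(ibm, "ibm_trajectories"))
  d <- dim(ibm$counts)
  long <- expand.grid(replicate = seq_len(d[1L]),
                      day = seq_len(d[2L]),
                      stage = ibm$stage_names,
                      KEEP.OUT.ATTRS = FALSE)
  long$date <- format(ibm$dates[long$day])
  long$count <- as.vector(ibm$counts)
  utils::write.csv(long[, c("replicate", "date", "stage", "count")],
                   path, row.names = FALSE, quote = FALSE)
  summ <- data.frame(date = rep(format(ibm$dates), times = length(ibm$stage_names)),
                     stage = rep(ibm$stage_names, each = d[2L]),
                     mean = as.vector(ibm$mean),
                     se = as.vector(ibm$se))
  utils::write.csv(summ, sub("\\.csv$", "_summary.csv", path),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
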