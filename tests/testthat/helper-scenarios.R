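# Shared fixtures: all built in code, no stored data.

# Constant-temperature forcing with all three channels explicit (no warning).
const_series <- function(n, tmean = 10, tmin = tmean, tmax = tmean,
                         start = "2020-01-01") {
  temperature_series(as.Date(start) + seq_len(n) - 1L,
                     tmin = rep_len(tmin, n), tmean = rep_len(tmean, n),
                     tmax = rep_len(tmax, n))
}

# Single-stage benchmark: median rate 0.5/day at 10 degC (linear curve),
# log-normal scale 0.2 -- the canonical demonstration configuration.
fig2_spec <- function(sigma = 0.2) {
  lognormal_rate_spec(
    rate_curve("linear_degree_day", base_temp = 0, slope = 0.05), sigma)
}
fig2_stage <- function(sigma = 0.2, gamma = 1) {
  stage_spec("s1", fig2_spec(sigma), gamma = gamma)
}

# Three linked stages with distinct rates and variability; constant 10 degC
# gives median rates 0.5, 0.4, 0.3 per day.
three_stage_specs <- function() {
  slopes <- c(0.05, 0.04, 0.03)
  sigmas <- c(0.2, 0.3, 0.15)
  mapply(function(sl, sg, nm) {
    stage_spec(nm, lognormal_rate_spec(
      rate_curve("linear_degree_day", base_temp = 0, slope = sl), sg))
  }, slopes, sigmas, c("a", "b", "c"), SIMPLIFY = FALSE)
}

# Brute-force weighted two-sample KS statistic by exhaustive ECDF
# enumeration; the oracle stays independent of the ecdf_pair machinery.
brute_ks_D <- function(x, wx, y, wy) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) sum(wx[x <= t]), 0) / sum(wx)
  Fy <- vapply(pts, function(t) sum(wy[y <= t]), 0) / sum(wy)
  max(abs(Fx - Fy))
}

# All multisets (as weight vectors over a fixed support) of total size <= n.
all_weighted_samples <- function(support, n_max) {
  k <- length(support)
  grids <- do.call(expand.grid, rep(list(0:n_max), k))
  sizes <- rowSums(grids)
  grids <- grids[sizes >= 1 & sizes <= n_max, , drop = FALSE]
  lapply(seq_len(nrow(grids)), function(i) {
    w <- as.numeric(grids[i, ])
    keep <- w > 0
    list(x = support[keep], w = w[keep])
  })
}
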