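test_that("kernels are normalized probability masses with the analytic mean", {
  grid <- age_grid(512L, a_max = 4)
  k <- build_kernel(fig2_spec(0.2), 10, 1, grid)
  expect_lt(abs(sum(k$increments) - 1), 1e-12)
  expect_true(all(k$increments >= 0))
  mean_k <- sum(grid$centers * k$increments)
  expect_lt(abs(mean_k - 0.5101), grid$bin_width)  # exp(mu + sigma^2/2)

  # randomly parameterized kernels all sum to one
  set.seed(4)
  for (i in 1:50) {
    sp <- lognormal_rate_spec(
      rate_curve("linear_degree_day", base_temp = 0,
                 slope = stats::runif(1, 0.001, 0.2)),
      sigma = stats::runif(1, 0.01, 0.6))
    g <- age_grid(sample(c(16L, 64L, 256L), 1), a_max = stats::runif(1, 2, 8))
    kk <- suppressWarnings(build_kernel(sp, stats::runif(1, 1, 30), 1, g))
    expect_lt(abs(sum(kk$increments) - 1), 1e-12)
  }
})

test_that("cold temperatures give the degenerate identity kernel", {
  grid <- age_grid(128L, a_max = 4)
  sp <- lognormal_rate_spec(rate_curve("linear_degree_day", base_temp = 5,
                                       slope = 0.01), 0.2)
  k <- build_kernel(sp, -10, 1, grid)
  expect_true(k$degenerate)
  expect_equal(k$increments[1L], 1)
  d <- age_distribution(grid, stats::runif(128))
  expect_identical(convolve_step(d, k), d)
})

test_that("convolution conserves mass, keeps overflow, and rejects grid mismatch", {
  grid <- age_grid(256L, a_max = 2)
  k <- build_kernel(fig2_spec(0.2), 10, 1, grid)
  d <- point_mass(grid, 100)
  for (i in 1:6) d <- convolve_step(d, k)
  expect_lt(abs(total_density(d) - 100) / 100, 1e-12)
  expect_gt(d$overflow, 0)  # mean age ~3 exceeds a_max = 2 by step 6
  d2 <- point_mass(age_grid(128L, a_max = 2), 1)
  expect_error(convolve_step(d2, k), "different grids")
})

test_that("repeated convolution reproduces the sum of iid log-normal draws", {
  grid <- age_grid(1024L, a_max = 8)
  k <- build_kernel(fig2_spec(0.2), 10, 1, grid)
  d <- point_mass(grid, 1)
  n_steps <- 5L
  for (i in seq_len(n_steps)) d <- convolve_step(d, k)
  m_ipm <- sum(grid$centers * d$mass) / sum(d$mass)
  v_ipm <- sum(grid$centers^2 * d$mass) / sum(d$mass) - m_ipm^2
  set.seed(99)
  n_mc <- 1e5
  mc <- colSums(matrix(stats::rlnorm(n_steps * n_mc, log(0.5), 0.2),
                       nrow = n_steps))
  se_mean <- stats::sd(mc) / sqrt(n_mc)
  expect_lt(abs(m_ipm - mean(mc)), 3 * se_mean)
  se_var <- stats::sd((mc - mean(mc))^2) / sqrt(n_mc)
  expect_lt(abs(v_ipm - stats::var(mc)), 3 * se_var)
})

test_that("mortality scales mass and validates its argument", {
  grid <- age_grid(64L, a_max = 4)
  d <- age_distribution(grid, rep(1.25, 64))  # total 80
  expect_identical(apply_mortality(d, 0), d)
  expect_equal(total_density(apply_mortality(d, 1)), 0)
  expect_equal(total_density(apply_mortality(d, 0.25)), 60)
  expect_error(apply_mortality(d, -0.1), "\\[0, 1\\]")
  expect_error(apply_mortality(d, 1.1), "\\[0, 1\\]")
})

test_that("the threshold split partitions mass exactly", {
  grid <- age_grid(128L, a_max = 4)
  below <- age_distribution(grid, ifelse(grid$centers < 1, 1, 0))
  s <- split_at_threshold(below, 1)
  expect_equal(s$crossed_mass, 0)
  expect_equal(s$retained$mass, below$mass)
  above <- age_distribution(grid, ifelse(grid$centers >= 1, 1, 0),
                            overflow = 5)
  s2 <- split_at_threshold(above, 1)
  expect_equal(s2$crossed_mass, total_density(above))
  expect_equal(total_density(s2$retained), 0)
  set.seed(2)
  mixed <- age_distribution(grid, stats::runif(128), overflow = 0.3)
  s3 <- split_at_threshold(mixed, 1)
  expect_equal(s3$crossed_mass + total_density(s3$retained),
               total_density(mixed))
})

test_that("a development- and mortality-free day is a fixed point", {
  stages <- list(fig2_stage(), three_stage_specs()[[2L]])
  state <- population_state(stages, age_grid(128L, a_max = 4),
                            counts = c(60, 40))
  res <- step_stage_system(state, list(tmin = -5, tmean = -5, tmax = -5),
                           stages, dt = 1)
  expect_equal(stage_totals(res$state), stage_totals(state))
  expect_equal(res$crossers, c(0, 0))
  expect_equal(res$deaths, 0)
  expect_equal(res$state$dists[[1L]]$mass, state$dists[[1L]]$mass)
})

test_that("near-deterministic development crosses at the rate-summation day", {
  # median rate 0.1/day, gamma 1: crossing day gamma/(r dt) = 10
  sp <- lognormal_rate_spec(rate_curve("linear_degree_day", base_temp = 0,
                                       slope = 0.01), 0.01)
  st <- stage_spec("s", sp, gamma = 1)
  traj <- suppressWarnings(
    simulate_ipm(const_series(15), list(st), init = 1))
  crossed <- cumsum(traj$recruitment[, 1L])
  expect_lt(crossed[9L], 0.5)
  expect_gte(crossed[10L], 0.5)
})

test_that("the per-step mass ledger balances through a multi-stage run", {
  stages <- three_stage_specs()
  traj <- simulate_ipm(const_series(20), stages, init = c(100, 0, 0),
                       grid = age_grid(256L, a_max = 4))
  ledger <- rowSums(traj$totals) + traj$emerged + traj$dead
  expect_true(all(abs(ledger - 100) / 100 < 1e-9))
})

test_that("truncation and difference-form recruitment bookkeeping agree", {
  st <- fig2_stage()
  ser <- const_series(10)
  grid <- age_grid(256L, a_max = 4)
  a <- simulate_ipm(ser, list(st), init = 100, grid = grid,
                    bookkeeping = "truncation")
  b <- simulate_ipm(ser, list(st), init = 100, grid = grid,
                    bookkeeping = "difference")
  expect_lt(max(abs(a$recruitment - b$recruitment)), 1e-10)
  expect_lt(max(abs(a$totals - b$totals)), 1e-10)
})

test_that("the cohort model is the same algorithm and converges with resolution", {
  stages <- three_stage_specs()
  ser <- const_series(15)
  ipm <- simulate_ipm(ser, stages, init = c(100, 0, 0))
  same <- simulate_cohort(ser, stages, init = c(100, 0, 0), n_bins = 128L)
  expect_identical(same$totals, ipm$totals)  # bit-for-bit at equal n_bins
  disc <- vapply(c(16L, 32L, 64L), function(nb) {
    co <- suppressWarnings(
      simulate_cohort(ser, stages, init = c(100, 0, 0), n_bins = nb))
    max(trajectory_discrepancy(co, ipm)$max_abs)
  }, 0)
  expect_true(all(diff(disc) <= 0))
  expect_gt(disc[1L], 0)
})

test_that("simulation is deterministic and totals match distribution sums", {
  stages <- three_stage_specs()
  ser <- const_series(12)
  t1 <- simulate_ipm(ser, stages, init = c(50, 25, 0))
  t2 <- simulate_ipm(ser, stages, init = c(50, 25, 0))
  expect_identical(t1$totals, t2$totals)
  expect_equal(unname(stage_totals(t1$final_state)),
               unname(t1$totals[nrow(t1$totals), ]))
})

test_that("total density sums bins, overflow, and point masses", {
  grid <- age_grid(64L, a_max = 4)
  expect_equal(total_density(point_mass(grid, 100)), 100)
  expect_equal(total_density(age_distribution(grid)), 0)
  a <- age_distribution(grid, ifelse(grid$centers < 2, 0.5, 0))
  b <- age_distribution(grid, ifelse(grid$centers >= 2, 0.25, 0))
  ab <- age_distribution(grid, a$mass + b$mass)
  expect_equal(total_density(ab), total_density(a) + total_density(b))
})
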