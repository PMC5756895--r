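test_that("cold-snap mortality is a step function with 'strictly below' semantics", {
  rule <- mortality_rule("cold_step")
  expect_equal(mortality_prob(rule, -10), 0)
  expect_equal(mortality_prob(rule, -20), 1)
  expect_equal(mortality_prob(rule, -18), 0)  # boundary: no kill
  expect_equal(mortality_prob(mortality_rule("none"), -40), 0)
})

test_that("flight is gated by tmax and settling follows exponential decay", {
  fm <- flight_model(settling_rate = log(2))  # one-day half-life
  cool <- flight_step(50, 0, tmax = 17, fm)
  expect_equal(cool$emerged, 50)
  expect_equal(cool$newly_flying, 0)
  warm <- flight_step(50, 0, tmax = 20, fm)
  expect_equal(warm$flying, 50)
  expect_equal(warm$emerged, 0)
  half <- flight_step(0, 100, tmax = 10, fm)
  expect_equal(half$newly_settled, 50)
  expect_equal(half$flying, 50)
  # conservation across pools
  mix <- flight_step(30, 100, tmax = 25, fm)
  expect_equal(mix$emerged + mix$flying + mix$newly_settled, 130)
})

test_that("start-time initialization distributes the brood by weight", {
  one <- initialize_from_start_times("2020-06-01", 1, egg_count = 82)
  expect_equal(one$mass, 82)
  two <- initialize_from_start_times(c("2020-06-01", "2020-06-08"), c(1, 1),
                                     egg_count = 82)
  expect_equal(two$mass, c(41, 41))
  many <- initialize_from_start_times(as.Date("2020-06-01") + 0:9,
                                      stats::runif(10), egg_count = 82)
  expect_equal(sum(many$mass), 82)
  expect_error(initialize_from_start_times("2020-06-01", 0), "zero")
})

test_that("the bundled life cycle has eight stages with larval cold immunity", {
  lc <- mpb_life_cycle()
  nm <- vapply(lc$stages, function(s) s$name, "")
  expect_equal(nm, c("egg", "L1", "L2", "L3", "L4", "pupa",
                     "teneral_adult", "adult"))
  kinds <- vapply(lc$stages, function(s) s$mortality$kind, "")
  expect_equal(kinds[c(1, 6, 7, 8)], rep("cold_step", 4))
  expect_equal(kinds[2:5], rep("none", 4))
  expect_equal(lc$flight$flight_threshold, 18.3)
})

test_that("one sub-threshold cold day kills exactly the cold-sensitive stages", {
  lc <- mpb_life_cycle()
  grid <- age_grid(128L, a_max = 4)
  state <- population_state(lc$stages, grid, counts = rep(10, 8))
  cold_day <- list(tmin = -20, tmean = -20, tmax = -15)
  res <- step_stage_system(state, cold_day, lc$stages, 1)
  tot <- stage_totals(res$state)
  expect_equal(unname(tot[c("egg", "pupa", "teneral_adult", "adult")]),
               rep(0, 4))
  expect_equal(unname(tot[c("L1", "L2", "L3", "L4")]), rep(10, 4))
  # a near-miss cold day kills nothing
  res2 <- step_stage_system(state, list(tmin = -17.9, tmean = -17.9,
                                        tmax = -15), lc$stages, 1)
  expect_equal(res2$deaths, 0)
})

test_that("the reference year runs the life cycle in order with overlapping broods", {
  lc <- mpb_life_cycle()
  series <- mpb_reference_forcing(seed = 1L)
  intro <- data.frame(date = as.Date("2014-07-30"), mass = 82)
  traj <- suppressWarnings(
    simulate_ipm(series, lc$stages, introductions = intro,
                 flight = lc$flight))
  peaks <- apply(traj$totals, 2L, which.max)
  expect_true(all(diff(peaks) >= 0))  # stage peaks in life-cycle order
  # L4, pupa, and teneral adult co-occur in early summer
  joint <- traj$totals[, "L4"] > 1e-6 & traj$totals[, "pupa"] > 1e-6 &
    traj$totals[, "teneral_adult"] > 1e-6
  expect_gt(sum(joint), 0)
  # every pool accounted for, every day
  ledger <- rowSums(traj$totals) + traj$emerged + traj$flying +
    traj$settled + traj$dead
  expect_true(all(abs(ledger - traj$introduced) <= 1e-9 * 82))
  # larval totals are invariant to tmin: rerun with brutal minima
  frozen <- series
  frozen$tmin <- pmin(frozen$tmin, -25)
  larv1 <- suppressWarnings(
    simulate_ipm(frozen, lc$stages, introductions = intro))
  # all mass dies in egg under permanent deep cold, larvae never killed
  expect_equal(max(larv1$dead), 82, tolerance = 1e-9)
})

test_that("cumulative flight curves are normalized and gated by the threshold", {
  lc <- mpb_life_cycle()
  series <- mpb_reference_forcing(seed = 1L)
  intro <- data.frame(date = as.Date("2014-07-30"), mass = 82)
  traj <- suppressWarnings(
    simulate_ipm(series, lc$stages, introductions = intro,
                 flight = lc$flight))
  curve <- cumulative_flight_curve(traj)
  expect_false(attr(curve, "empty"))
  expect_true(all(diff(curve$cumulative_fraction) >= 0))
  expect_true(all(curve$cumulative_fraction <= 1))
  expect_equal(curve$cumulative_fraction[nrow(curve)], 1)
  expect_true(all(traj$newly_flown[series$tmax <= 18.3] == 0))
  # no warm days: flagged empty curve, not an error
  chilly <- traj
  chilly$newly_flown[] <- 0
  empty <- cumulative_flight_curve(chilly)
  expect_true(attr(empty, "empty"))
  expect_true(all(empty$cumulative_fraction == 0))
})

test_that("trap series normalize their cumulative catch", {
  tr <- trap_series(as.Date("2020-06-01") + c(10, 0, 5), c(3, 1, 0))
  expect_equal(tr$count, c(1, 0, 3))  # reordered by date
  expect_equal(tr$normalized_cumulative, c(0.25, 0.25, 1))
  expect_error(trap_series("2020-06-01", -1), "nonnegative")
})
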