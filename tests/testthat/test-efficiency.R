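test_that("per-period consumption is the reservoir drop, extrapolated hourly", {
  out <- consumption_per_period(c(250, 249.85, 249.7), c(0, 200, 400),
                                data.frame(t_start = 0, t_end = 600))
  expect_equal(out$liquid_consumed_ml, 0.3)
  expect_equal(out$hourly_rate_ml_h, 1.8)
  # constant reservoir: zero consumption
  flat <- consumption_per_period(rep(100, 5), (0:4) * 60,
                                 data.frame(t_start = 0, t_end = 300))
  expect_equal(flat$liquid_consumed_ml, 0)
  expect_equal(flat$hourly_rate_ml_h, 0)
  # a refilling reservoir is a data error
  expect_error(consumption_per_period(c(100, 101), c(0, 60),
                                      data.frame(t_start = 0, t_end = 120)),
               "data error")
})

test_that("per-period consumption equals ground-truth injections over each period", {
  sim <- quick_sim(seed = 8, fractions = c(0.6, 1.0), duration = 600)
  gt <- sim$ground_truth
  periods <- sim$schedule
  cons <- consumption_per_period(sim$device_log$reservoir_ml, gt$t_start, periods,
                                 initial_ml = sim$reservoir_ml)
  for (p in seq_len(nrow(periods))) {
    in_p <- gt$t_start >= periods$t_start[p] & gt$t_start < periods$t_end[p]
    expect_equal(cons$liquid_consumed_ml[p],
                 sum(gt$injected_ml[in_p]) / sim$agent$vapour_factor_f,
                 tolerance = 1e-9)
  }
})

test_that("reflection efficiency reproduces the consumption formula", {
  expect_equal(reflection_efficiency(4, 200, 0.4, 500, 10), 100 / 3)
  expect_equal(reflection_efficiency(0, 200, 1.0, 500, 10), 100)
  # overload: more vapour delivered than an open system would need
  expect_equal(reflection_efficiency(43, 193, 2.6, 500, 10), -6.397, tolerance = 1e-3)
  expect_error(reflection_efficiency(4, 200, 0, 500, 10), "steady-state")
  # strictly decreasing in IR, increasing in EC, VT, RR
  expect_true(all(diff(reflection_efficiency(1:5, 200, 0.5, 500, 10)) < 0))
  expect_true(all(diff(reflection_efficiency(4, 200, c(0.3, 0.5, 1, 2), 500, 10)) > 0))
  expect_true(all(diff(reflection_efficiency(4, 200, 0.5, c(300, 500, 700), 10)) > 0))
  expect_true(all(diff(reflection_efficiency(4, 200, 0.5, 500, c(8, 10, 12))) > 0))
})

test_that("vapour per breath is EC x VT / 100 and scale-compensating", {
  sim <- quick_sim(seed = 12, fractions = c(0.5, 1.0), duration = 300)
  br <- suppressMessages(suppressWarnings(analyze_breaths(sim$trace)))
  eff <- efficiency_table(br, sim$device_log, sim$schedule, sim$vent, sim$agent)
  expect_equal(eff$vapour_per_breath_ml,
               eff$mean_ec / 100 * sim$vent$tidal_volume)
  # doubling EC while halving VT leaves the vapour volume unchanged
  expect_equal((2 * eff$mean_ec) / 100 * (sim$vent$tidal_volume / 2),
               eff$vapour_per_breath_ml)
})

test_that("ascending and descending periods average into one record per target", {
  sim <- quick_sim(seed = 14, fractions = c(0.4, 0.8, 0.4), duration = 240)
  br <- suppressMessages(suppressWarnings(analyze_breaths(sim$trace)))
  eff <- efficiency_table(br, sim$device_log, sim$schedule, sim$vent, sim$agent)
  avg <- average_up_down(eff)
  expect_equal(nrow(avg), 2)
  expect_equal(avg$n_periods, c(2, 1))
  i04 <- eff$target_mac == 0.4
  expect_equal(avg$hourly_rate_ml_h[1], mean(eff$hourly_rate_ml_h[i04]))
  expect_equal(avg$mean_ec[1], mean(eff$mean_ec[i04]))
  # singleton target passes through unchanged
  expect_equal(avg$hourly_rate_ml_h[2], eff$hourly_rate_ml_h[!i04])
  # simple mean oracle
  r <- eff
  r$hourly_rate_ml_h <- c(1.2, 99, 1.6)[seq_len(nrow(r))]
  r$hourly_rate_ml_h[!i04] <- 99
  r$hourly_rate_ml_h[i04] <- c(1.2, 1.6)
  expect_equal(average_up_down(r)$hourly_rate_ml_h[1], 1.4)
})

test_that("the full staircase yields 8 per-target records from 15 periods", {
  sim <- simulate_experiment(seed = 31)
  br <- suppressMessages(suppressWarnings(analyze_breaths(sim$trace)))
  eff <- efficiency_table(br, sim$device_log, sim$schedule, sim$vent, sim$agent)
  expect_equal(nrow(eff), 15)
  avg <- average_up_down(eff)
  expect_equal(nrow(avg), 8)
  expect_equal(avg$n_periods, c(rep(2, 7), 1))
  # low targets are flagged for RE summaries but never dropped
  expect_equal(sum(avg$low_target), 2)   # 0.2 and 0.4 MAC
  expect_equal(sum(eff$low_target), 4)
})

test_that("greenhouse-gas savings multiply out explicitly", {
  expect_equal(co2e_savings(2, 1.50, 1.9, 24), 136.8)
  expect_equal(co2e_savings(0, 1.50, 1.9, 24), 0)
  expect_equal(co2e_savings(1, 1, 1, 1), 1)
  expect_error(co2e_savings(-1, 1, 1, 1), "non-negative")
})
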