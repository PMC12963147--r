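test_that("Bland-Altman bias and limits match closed-form arithmetic", {
  # identical channels: zero bias, zero-width limits
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$bias, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)
  # differences +0.1 / -0.1: sd = 0.1 * sqrt(2), limits = +/- 1.96 sd
  ba <- bland_altman(c(1.1, 0.9), c(1.0, 1.0))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(2) * 0.1, tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * sqrt(2) * 0.1, tolerance = 1e-12)
  expect_equal(ba$loa_low, -ba$loa_high)
  expect_equal(ba$n, 2)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Bland-Altman drops incomplete pairs and is antisymmetric", {
  x <- c(1.0, 1.2, NA, 1.4, 1.1)
  y <- c(1.1, 1.1, 1.0, NA, 1.0)
  ba <- bland_altman(x, y)
  expect_equal(ba$n, 3)
  swapped <- bland_altman(y, x)
  expect_equal(swapped$bias, -ba$bias)
  expect_equal(swapped$loa_low, -ba$loa_high)
  expect_equal(swapped$loa_high, -ba$loa_low)
  expect_equal(swapped$pairs$mean, ba$pairs$mean)
})

test_that("with equal-noise channels and no offset the bias is tiny", {
  # n = 1600, both channels sd 0.02: |bias| < 3 se = 3 * 0.02 * sqrt(2/1600)
  set.seed(123)
  truth <- runif(1600, 0.2, 2)
  ba <- bland_altman(truth + rnorm(1600, 0, 0.02), truth + rnorm(1600, 0, 0.02))
  expect_lt(abs(ba$bias), 3 * 0.02 * sqrt(2 / 1600))
  expect_lt(abs(ba$bias), 0.005)
})

test_that("polynomial consumption fits interpolate exact parabolas", {
  ec <- c(0.3, 0.6, 0.9, 1.2, 1.5, 1.8)
  rate <- 0.5 + 1.2 * ec + 0.8 * ec^2
  fit <- fit_consumption(data.frame(group = "iso_long", mean_ec = ec,
                                    hourly_rate_ml_h = rate))
  expect_equal(unname(fit$coefficients$iso_long), c(0.5, 1.2, 0.8),
               tolerance = 1e-9)
  expect_equal(predict_consumption(fit, "iso_long", c(0.5, 1.0)),
               0.5 + 1.2 * c(0.5, 1.0) + 0.8 * c(0.5, 1.0)^2,
               tolerance = 1e-9)
  # equivariance: scaling consumption scales coefficients linearly
  fit2 <- fit_consumption(data.frame(group = "iso_long", mean_ec = ec,
                                     hourly_rate_ml_h = 3 * rate))
  expect_equal(unname(fit2$coefficients$iso_long),
               3 * unname(fit$coefficients$iso_long), tolerance = 1e-9)
})

test_that("degenerate designs and short groups are rejected by name", {
  bad <- data.frame(group = "g1", mean_ec = c(1, 1, 1, 1, 1),
                    hourly_rate_ml_h = 1:5)
  expect_error(fit_consumption(bad), "g1")
  short <- data.frame(group = "tiny", mean_ec = c(1, 2, 3),
                      hourly_rate_ml_h = 1:3)
  expect_error(fit_consumption(short), "tiny")
})

test_that("group contrasts keep their type-I error under the null", {
  # identical curves + noise: the group effect should rarely be significant
  ec <- rep(seq(0.3, 1.8, length.out = 8), 2)
  curve <- 0.4 + 1.5 * ec + 0.6 * ec^2
  set.seed(202)
  n_sig <- 0
  for (rep in 1:100) {
    d <- data.frame(group = rep(c("a", "b"), each = 8), mean_ec = ec,
                    hourly_rate_ml_h = curve + rnorm(16, 0, 0.2))
    f <- fit_consumption(d)
    if (f$contrasts$p_value < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 10)   # >= 90% non-significant over 100 null replicates
})

test_that("exclusions remove the named targets before fitting and contrasts", {
  ec <- seq(0.4, 2.8, length.out = 10)
  d <- rbind(
    data.frame(group = "sevo", target_volpct = ec, mean_ec = ec,
               hourly_rate_ml_h = 1 + 2 * ec + 0.5 * ec^2),
    data.frame(group = "iso", target_volpct = ec, mean_ec = ec,
               hourly_rate_ml_h = 1 + 2 * ec + 0.5 * ec^2))
  excl <- data.frame(group = "sevo", target_volpct = tail(ec, 3))
  f <- fit_consumption(d, exclusions = excl)
  expect_equal(sum(f$data$group == "sevo"), 7)
  expect_equal(sum(f$data$group == "iso"), 10)
})

test_that("the report bundle writes deterministic CSVs that round-trip", {
  sim <- quick_sim(seed = 19, fractions = c(0.5, 1.0), duration = 300)
  br <- suppressMessages(suppressWarnings(analyze_breaths(sim$trace)))
  eff <- efficiency_table(br, sim$device_log, sim$schedule, sim$vent, sim$agent,
                          initial_reservoir_ml = sim$reservoir_ml)
  avg <- average_up_down(eff)
  n <- min(nrow(br), nrow(sim$device_log))
  ba <- bland_altman(sim$device_log$device_ec_volpct[seq_len(n)],
                     br$ec_volpct[seq_len(n)])
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(render_report(d1, breaths = br, device_log = sim$device_log,
                                 schedule = sim$schedule, vent = sim$vent,
                                 agent = sim$agent, agreement = ba,
                                 efficiency = eff, averaged = avg,
                                 formats = "csv"))
  suppressMessages(render_report(d2, breaths = br, device_log = sim$device_log,
                                 schedule = sim$schedule, vent = sim$vent,
                                 agent = sim$agent, agreement = ba,
                                 efficiency = eff, averaged = avg,
                                 formats = "csv"))
  files <- list.files(d1)
  expect_true(all(c("ec_timecourse.csv", "ec_target_means.csv",
                    "bland_altman_summary.csv", "efficiency_periods.csv",
                    "efficiency_targets.csv") %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # round-trip: re-reading reproduces the written table
  again <- utils::read.csv(file.path(d1, "efficiency_targets.csv"))
  expect_equal(again$hourly_rate_ml_h, round(avg$hourly_rate_ml_h, 4))
  # per-target mean entries: one per period
  means <- utils::read.csv(file.path(d1, "ec_target_means.csv"))
  expect_equal(nrow(means), nrow(sim$schedule))
})

test_that("report sections without inputs are skipped with a notice", {
  sim <- quick_sim(seed = 23, fractions = 0.5, duration = 120)
  br <- suppressMessages(suppressWarnings(analyze_breaths(sim$trace)))
  ba <- bland_altman(sim$device_log$device_ec_volpct[seq_len(nrow(br))],
                     br$ec_volpct)
  d <- withr::local_tempdir()
  expect_message(render_report(d, agreement = ba, formats = "csv"),
                 "skipped")
  files <- list.files(d)
  expect_true("bland_altman_summary.csv" %in% files)
  expect_false("efficiency_periods.csv" %in% files)
})
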