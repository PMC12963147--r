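test_that("supra-threshold CO2 runs are found exactly, with strict inequality", {
  # hand-built: 60 samples, CO2 > 34 at indices 10..39
  tr <- handmade_trace(agent = rep(1, 60), start = 10, run_len = 30)
  runs <- segment_breaths(tr)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$start, 10)
  expect_equal(runs$end, 39)
  expect_equal(runs$n_samples, 30)
  # samples exactly at the threshold do not count as expiration
  tr34 <- gas_trace(agent = rep(1, 20), co2 = rep(34, 20))
  expect_equal(nrow(segment_breaths(tr34)), 0)
  # empty and all-zero traces yield no runs
  expect_equal(nrow(segment_breaths(gas_trace(numeric(0), numeric(0)))), 0)
  expect_equal(nrow(segment_breaths(gas_trace(rep(1, 50), rep(0, 50)))), 0)
  expect_error(segment_breaths(tr, co2_threshold = 0), "positive")
})

test_that("short blips are debounced; distinct breaths give distinct runs", {
  co2 <- rep(5, 100)
  co2[10:39] <- 40          # a breath
  co2[50:51] <- 40          # a 0.2 s blip: noise
  co2[60:89] <- 40          # another breath
  tr <- gas_trace(agent = rep(0.5, 100), co2 = co2)
  runs <- segment_breaths(tr)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$start, c(10, 60))
})

test_that("the end-tidal window averages 20 samples from 0.2 s after run onset", {
  # agent 0.50 + 0.01k over the window samples -> mean 0.595
  agent <- rep(0.3, 60)
  agent[12:31] <- 0.50 + 0.01 * (0:19)
  tr <- handmade_trace(agent, start = 10, run_len = 30)
  runs <- segment_breaths(tr)
  expect_equal(ec_window_indices(tr, runs[1, ]), 12:31)
  expect_equal(compute_ec(tr, runs[1, ]), 0.595)
  # a constant channel returns the constant
  trc <- handmade_trace(rep(1.00, 60), start = 10, run_len = 30)
  expect_equal(compute_ec(trc, segment_breaths(trc)[1, ]), 1.00)
  # 30-sample run: the last 8 supra-threshold samples are excluded
  expect_equal(max(ec_window_indices(tr, runs[1, ])), runs$end - 8)
})

test_that("runs too short for the window are flagged incomplete", {
  tr <- handmade_trace(rep(1, 60), start = 10, run_len = 21)
  runs <- segment_breaths(tr)
  expect_warning(ec <- compute_ec(tr, runs[1, ]), "incomplete|missing")
  expect_true(is.na(ec))
  expect_length(ec_window_indices(tr, runs[1, ]), 0)
})

test_that("end-tidal extraction is translation invariant", {
  sim <- quick_sim(seed = 13, fractions = 0.8, duration = 120)
  runs <- segment_breaths(sim$trace)
  shifted <- gas_trace(sim$trace$agent + 0.37, sim$trace$co2)
  for (i in c(1, 5, nrow(runs) - 1)) {
    expect_equal(compute_ec(shifted, runs[i, ]),
                 compute_ec(sim$trace, runs[i, ]) + 0.37)
  }
})

test_that("peak metrics follow the positive-excess counting rules", {
  # inspiratory window with excesses 0.5, 1.0, 0.5 above the next EC of 1.0
  agent <- c(rep(1, 10), 1.5, 2.0, 1.5, rep(0.8, 7))
  tr <- gas_trace(agent, co2 = rep(5, 20))
  pk <- quantify_peak(tr, 11, 20, next_ec = 1.0)
  expect_equal(pk$t_inj, 0.3)
  expect_equal(pk$auc, 0.2)
  expect_equal(pk$cpeak, 2.0)
  expect_true(pk$peak_present)
  # nothing above the next EC: no peak
  flat <- quantify_peak(tr, 14, 20, next_ec = 1.0)
  expect_equal(flat$t_inj, 0)
  expect_equal(flat$auc, 0)
  expect_false(flat$peak_present)
  # auc = 0 iff t_inj = 0 over assorted windows
  for (ws in c(1, 5, 11)) {
    p <- quantify_peak(tr, ws, 20, next_ec = 1.2)
    expect_equal(p$auc == 0, p$t_inj == 0)
  }
})

test_that("peak AUC ignores sample order; injection time counts only positives", {
  base <- c(0.2, 1.7, 0.9, 1.4, 0.1, 0.1, 2.2, 0.3)
  tr1 <- gas_trace(base, rep(5, 8))
  tr2 <- gas_trace(rev(base), rep(5, 8))
  p1 <- quantify_peak(tr1, 1, 8, next_ec = 0.8)
  p2 <- quantify_peak(tr2, 1, 8, next_ec = 0.8)
  expect_equal(p1$auc, p2$auc)
  expect_equal(p1$t_inj, p2$t_inj)
  expect_equal(p1$t_inj, 4 / 10)
})

test_that("the peak gate suppresses noise-only windows", {
  set.seed(99)
  agent <- 1 + rnorm(30, 0, 0.01)
  tr <- gas_trace(agent, rep(5, 30))
  pk <- quantify_peak(tr, 1, 30, next_ec = 1.0)
  expect_false(pk$peak_present)          # excesses exist but are tiny
  expect_true(pk$t_inj > 0)              # raw counting is still reported
})

test_that("breath-by-breath evaluation recovers the simulator ground truth", {
  sim <- quick_sim(seed = 17, fractions = c(0.6, 1.2), duration = 300,
                   noise_sd = 0, co2_noise_sd = 0)
  br <- suppressMessages(suppressWarnings(analyze_breaths(sim$trace)))
  gt <- sim$ground_truth
  # run count equals the true breath count exactly
  expect_equal(nrow(br), nrow(gt))
  # noise-free ECs match the lung plateau to the monitor's resolution
  ok <- !is.na(br$ec_volpct)
  expect_true(all(abs(br$ec_volpct[ok] - gt$lung_volpct[ok]) <= 0.01))
  # detected peaks only on breaths where the controller actually fired
  # (peak windows sit between run k and k+1 = inspiration of breath k+1)
  fired <- which(br$peak_present[-nrow(br)])
  expect_true(all(gt$injected_ml[fired + 1] > 0))
})

test_that("detected peak durations and areas stay in the bench-observed ranges", {
  for (agent in list(agent_spec("isoflurane"), agent_spec("sevoflurane"))) {
    sim <- simulate_experiment(agent = agent, seed = 42)
    br <- suppressMessages(suppressWarnings(analyze_breaths(sim$trace)))
    pk <- br[br$peak_present, ]
    expect_gt(nrow(pk), 100)
    expect_true(all(pk$t_inj_s >= 0.4 & pk$t_inj_s <= 4.3))
    expect_true(all(pk$auc_volpcts >= 0.4 & pk$auc_volpcts <= 5.4))
  }
})
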