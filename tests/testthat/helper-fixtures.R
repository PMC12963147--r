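# Shared fixtures: all built in code, nothing stored on disk.

# A short closed-loop simulation (a few constant-target periods) that is
# cheap enough for unit tests.
quick_sim <- function(seed = 11, fractions = c(0.5, 1.0), duration = 300, ...) {
  simulate_experiment(schedule = target_schedule(fractions, duration),
                      seed = seed, ...)
}

# Hand-built single-breath trace: CO2 exceeds 34 mmHg for exactly
# `run_len` samples starting at `start` (1-based), agent as supplied.
handmade_trace <- function(agent, start, run_len, n = length(agent),
                           plateau = 40, floor = 5) {
  co2 <- rep(floor, n)
  co2[start:(start + run_len - 1)] <- plateau
  gas_trace(agent = agent, co2 = co2)
}

expect_no_spill <- function(sim) {
  expect_true(all(sim$ground_truth$inj_spill_ml == 0))
}
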