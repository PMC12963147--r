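#' Anaesthetic reflector parameters
#'
#' Physical behaviour of the activated-carbon reflector and of the gas
#' interface around the sampling port.
#'
#' @param base_efficiency Fraction (0-1) of the vapour exhaled from the lung
#'   that the reflector adsorbs and resupplies on the next inspiration,
#'   before any capacity limit.
#' @param capacity_per_breath Maximum mL of vapour the reflector can store
#'   per breath; vapour beyond it is vented irreversibly.
#' @param interface_retention_time Seconds of expired gas retained in the
#'   interface and washed past the sampling port at early inspiration; this
#'   delays the whole expirogram at the port.
#' @param co2_reflection_floor Inspiratory CO2 baseline in mmHg (the
#'   reflector also reflects a little CO2, so the trace does not fall to 0).
#' @param dead_volume mL of interface + HME + hose volume over which a
#'   spilled vapour cloud is diluted when it is seen at the sampling port.
#' @param sat_volpct Saturated-vapour ceiling (vol%) for displayed
#'   concentrations at the port.
#' @return An object of class `reflector_params`.
#' @export
reflector_params <- function(base_efficiency = 0.85,
                             capacity_per_breath = 12,
                             interface_retention_time = 1.0,
                             co2_reflection_floor = 5,
                             dead_volume = 400,
                             sat_volpct = 30) {
  if (base_efficiency < 0 || base_efficiency > 1)
    stop("base_efficiency must lie in [0, 1]")
  if (capacity_per_breath <= 0) stop("capacity_per_breath must be positive (mL vapour)")
  if (interface_retention_time < 0) stop("interface_retention_time must be non-negative")
  if (co2_reflection_floor < 0) stop("co2_reflection_floor must be non-negative")
  structure(list(base_efficiency = base_efficiency,
                 capacity_per_breath = capacity_per_breath,
                 interface_retention_time = interface_retention_time,
                 co2_reflection_floor = co2_reflection_floor,
                 dead_volume = dead_volume,
                 sat_volpct = sat_volpct),
            class = "reflector_params")
}

#' Vapour injector / target controller parameters
#'
#' The real device's control algorithm is proprietary; this controller
#' reproduces its observed phenomenology: when the device's end-tidal
#' estimate falls a hysteresis below the target, a series of inspiratory
#' injections starts and continues until the estimate reaches the target
#' again. The estimate is an exponentially smoothed per-breath end-tidal
#' concentration, which lags the lung and so produces the overshoot and the
#' multi-injection series seen on the bench. Injection is rate-limited;
#' whatever cannot be delivered within the inspiratory-flow time spills into
#' the inspiratory pause as a stagnant vapour cloud.
#'
#' @param mode `"target"` (closed-loop), `"constant"` (a fixed volume every
#'   breath, for steady-state oracles) or `"off"`.
#' @param vapour_rate Deliverable vapour in mL/s; 0 disables injection.
#' @param gain Fraction of the estimated concentration deficit (scaled to
#'   the lung + tidal gas volume) requested per breath while a series runs.
#' @param trigger_hysteresis vol% below target at which a series starts.
#' @param min_pulse_time Minimum duration (s) of a single injection pulse.
#' @param ec_alpha Smoothing weight of the controller's end-tidal estimate
#'   (1 = no smoothing, no lag).
#' @param constant_ml mL vapour per breath in `"constant"` mode.
#' @return An object of class `injector_params`.
#' @export
injector_params <- function(mode = c("target", "constant", "off"),
                            vapour_rate = 3,
                            gain = 0.8,
                            trigger_hysteresis = 0.10,
                            min_pulse_time = 0.5,
                            ec_alpha = 0.3,
                            constant_ml = 0) {
  mode <- match.arg(mode)
  if (vapour_rate < 0) stop("vapour_rate must be non-negative (mL vapour / s)")
  if (mode != "off" && vapour_rate == 0) mode <- "off"
  if (gain <= 0 || gain > 4) stop("gain must lie in (0, 4]")
  if (trigger_hysteresis < 0) stop("trigger_hysteresis must be non-negative (vol%)")
  if (ec_alpha <= 0 || ec_alpha > 1) stop("ec_alpha must lie in (0, 1]")
  if (constant_ml < 0) stop("constant_ml must be non-negative")
  structure(list(mode = mode, vapour_rate = vapour_rate, gain = gain,
                 trigger_hysteresis = trigger_hysteresis,
                 min_pulse_time = min_pulse_time,
                 ec_alpha = ec_alpha, constant_ml = constant_ml),
            class = "injector_params")
}

#' Simulate a bench experiment
#'
#' Seeded breath-by-breath simulation of a reflection-based delivery system
#' ventilating a single-compartment test lung (fixed volume, perfect mixing,
#' no wall uptake). Produces the 10 Hz dual-channel gas trace a side-stream
#' monitor would record at the sampling port, the device's per-breath log
#' (noisy end-tidal estimate and reservoir level) and the exact per-breath
#' vapour bookkeeping.
#'
#' Per breath: vapour injected within the inspiratory-flow time and vapour
#' desorbed from the reflector enter the lung mix; a tidal volume is exhaled
#' at the mixed concentration; injection demand exceeding the flow time
#' accumulates as a stagnant cloud during the pause and is pushed against
#' the reflector at expiration, where it counts against the per-breath
#' capacity first; reflector capture beyond capacity is vented irreversibly;
#' the liquid reservoir falls by injected vapour / F.
#'
#' @param vent A [vent_settings()]; the 10 Hz sampling requires the cycle to
#'   be a whole number of 100 ms samples.
#' @param agent An [agent_spec()].
#' @param schedule A [target_schedule()].
#' @param reflector A [reflector_params()].
#' @param injector An [injector_params()].
#' @param noise_sd Additive Gaussian noise sd on the agent channel (vol%).
#' @param co2_noise_sd Additive Gaussian noise sd on the CO2 channel (mmHg).
#' @param device_noise_sd Noise sd of the device's logged end-tidal values
#'   (vol%), drawn from an independent sub-stream.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param lung_volume Test-lung volume in mL.
#' @param reservoir_ml Initial liquid anaesthetic in the reservoir (mL).
#' @param init_lung_volpct Initial lung concentration (vol%).
#' @param etco2 End-tidal CO2 plateau (mmHg); default drawn uniformly in
#'   35-45 once per experiment.
#' @return An object of class `acd_sim`: a list with elements `trace`
#'   (a [gas_trace()]), `device_log`, `ground_truth` (data.frames),
#'   `status` (`"completed"` or `"reservoir_exhausted"`), `etco2`, and the
#'   input configuration.
#' @examples
#' sim <- simulate_experiment(schedule = target_schedule(0.5, 120), seed = 1)
#' nrow(sim$ground_truth)  # 20 breaths
#' @export
simulate_experiment <- function(vent = vent_settings(),
                                agent = agent_spec("isoflurane"),
                                schedule = staircase_schedule(),
                                reflector = reflector_params(),
                                injector = injector_params(),
                                noise_sd = 0.01,
                                co2_noise_sd = 0.1,
                                device_noise_sd = 0.02,
                                seed = 1L,
                                lung_volume = 3000,
                                reservoir_ml = 250,
                                init_lung_volpct = 0,
                                etco2 = NULL) {
  stopifnot(inherits(vent, "vent_settings"), inherits(agent, "agent_spec"),
            inherits(schedule, "target_schedule"),
            inherits(reflector, "reflector_params"),
            inherits(injector, "injector_params"))
  if (noise_sd < 0 || co2_noise_sd < 0 || device_noise_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (lung_volume <= 0) stop("lung_volume must be positive (mL)")
  if (reservoir_ml < 0) stop("reservoir_ml must be non-negative (mL liquid)")

  dt <- 0.1
  ph <- phase_durations(vent)
  tf <- ph[["flow_time"]]; tp <- ph[["pause_time"]]; te <- ph[["expiration_time"]]
  ti <- tf + tp
  cycle <- ti + te
  if (abs(cycle / dt - round(cycle / dt)) > 1e-9)
    stop("breath cycle must be a whole number of 100 ms samples")
  if (reflector$interface_retention_time >= ti)
    stop("interface_retention_time must be shorter than the inspiration")

  total_s <- schedule_duration(schedule)
  n_breaths <- floor(total_s / cycle + 1e-9)  # incomplete trailing breaths dropped
  n_samples <- round(total_s / dt)
  vt <- vent$tidal_volume
  f_flow <- vent$inspiratory_flow * 1000 / 60      # mL/s
  v_mix <- lung_volume + vt
  d <- reflector$interface_retention_time

  # device-log EC noise: independent sub-stream so trace noise is unaffected
  sub_seed <- (as.integer(seed) + 1013904223L) %% 2147483647L
  set.seed(sub_seed)
  dev_noise <- stats::rnorm(n_breaths, 0, device_noise_sd)

  set.seed(as.integer(seed))
  if (is.null(etco2)) etco2 <- stats::runif(1, 35, 45)
  floor_co2 <- reflector$co2_reflection_floor

  agent_ch <- numeric(n_samples)
  co2_ch <- rep(floor_co2, n_samples)

  paint <- function(ch, t0, t1, value) {
    # half-open [t0, t1): sample i (1-based) covers [(i-1)*dt, i*dt)
    i0 <- max(1L, as.integer(ceiling(t0 / dt - 1e-9)) + 1L)
    i1 <- min(n_samples, as.integer(ceiling(t1 / dt - 1e-9)))
    if (i1 >= i0) ch[i0:i1] <- value
    ch
  }
  ramp <- function(ch, t0, t1, v0, v1) {
    i0 <- max(1L, as.integer(ceiling(t0 / dt - 1e-9)) + 1L)
    i1 <- min(n_samples, as.integer(ceiling(t1 / dt - 1e-9)))
    if (i1 >= i0) {
      tt <- ((i0:i1) - 1) * dt
      ch[i0:i1] <- v0 + (v1 - v0) * (tt - t0) / (t1 - t0)
    }
    ch
  }

  # state
  lung_vap <- init_lung_volpct / 100 * lung_volume
  reflector_store <- 0
  cloud <- 0
  injected_cum <- 0
  ctrl_ec <- init_lung_volpct
  series_active <- FALSE
  status <- "completed"

  gt <- data.frame(
    breath_index = seq_len(n_breaths), t_start = (seq_len(n_breaths) - 1) * cycle,
    target_volpct = 0, lung_volpct = 0, injected_ml = 0, inj_flow_ml = 0,
    inj_spill_ml = 0, released_ml = 0, exhaled_ml = 0, captured_ml = 0,
    vented_ml = 0, reservoir_ml = 0, n_injections_active = 0)

  cap <- reflector$capacity_per_breath
  eff <- reflector$base_efficiency
  rate <- injector$vapour_rate
  last_breath <- n_breaths

  for (k in seq_len(n_breaths)) {
    t0 <- (k - 1) * cycle
    target <- schedule_target_at(schedule, t0, agent)

    # controller end-tidal estimate (smoothed -> lags the lung)
    ctrl_ec <- (1 - injector$ec_alpha) * ctrl_ec +
      injector$ec_alpha * (100 * lung_vap / lung_volume)

    inj_total <- 0
    if (injector$mode == "target" && rate > 0 && target > 0) {
      if (!series_active && ctrl_ec < target - injector$trigger_hysteresis)
        series_active <- TRUE
      if (series_active && ctrl_ec >= target) series_active <- FALSE
      if (series_active) {
        demand <- injector$gain * (target - ctrl_ec) / 100 * v_mix
        demand <- max(demand, rate * injector$min_pulse_time)
        inj_total <- min(demand, rate * ti)
      }
    } else if (injector$mode == "constant") {
      inj_total <- min(injector$constant_ml, rate * ti)
    }
    available_vap <- (reservoir_ml - injected_cum / agent$vapour_factor_f) *
      agent$vapour_factor_f
    if (inj_total > available_vap) {
      status <- "reservoir_exhausted"
      last_breath <- k - 1
      break
    }
    inj_flow <- min(inj_total, rate * tf)
    inj_spill <- inj_total - inj_flow

    # gas exchange
    release <- reflector_store
    reflector_store <- 0
    lung_vap <- lung_vap + inj_flow + release
    conc <- 100 * lung_vap / v_mix
    exhaled_lung <- lung_vap * vt / v_mix
    lung_vap <- lung_vap - exhaled_lung
    cloud <- cloud + inj_spill
    exhaled_total <- exhaled_lung + cloud
    # the cloud is pushed against the reflector at expiration and counts
    # against capacity first; capture is efficiency- and capacity-limited
    captured <- min(eff * exhaled_total, cap)
    vented <- exhaled_total - captured
    reflector_store <- captured
    cloud <- 0
    injected_cum <- injected_cum + inj_total
    reservoir_now <- reservoir_ml - injected_cum / agent$vapour_factor_f

    gt$target_volpct[k] <- target
    gt$lung_volpct[k] <- conc
    gt$injected_ml[k] <- inj_total
    gt$inj_flow_ml[k] <- inj_flow
    gt$inj_spill_ml[k] <- inj_spill
    gt$released_ml[k] <- release
    gt$exhaled_ml[k] <- exhaled_total
    gt$captured_ml[k] <- captured
    gt$vented_ml[k] <- vented
    gt$reservoir_ml[k] <- reservoir_now
    gt$n_injections_active[k] <- as.integer(inj_total > 0)

    # ---- paint the port trace ----
    # inspiratory gas reaches the port after the retained expired gas clears
    b <- 100 * release / vt                       # reflected baseline, vol%
    agent_ch <- paint(agent_ch, t0 + d, t0 + ti + d, b)
    if (inj_total > 0) {
      t_inj <- inj_total / rate
      h_flow <- b + 100 * rate / f_flow
      agent_ch <- paint(agent_ch, t0 + d, t0 + d + min(t_inj, tf), h_flow)
      if (inj_spill > 0) {
        h_cloud <- min(100 * inj_spill / reflector$dead_volume + conc,
                       reflector$sat_volpct)
        agent_ch <- paint(agent_ch, t0 + d + tf, t0 + d + min(t_inj, ti), h_cloud)
      }
    }
    # expired gas at the port: ramped expirogram, delayed by the retention time
    ws <- t0 + ti + d
    we <- t0 + cycle + d
    agent_ch <- paint(agent_ch, ws - 0.2, we, conc)
    co2_ch <- ramp(co2_ch, ws - 0.2, ws + 0.2, floor_co2, etco2)
    co2_ch <- paint(co2_ch, ws + 0.2, we, etco2)
    co2_ch <- ramp(co2_ch, we, we + 0.3, etco2, floor_co2)
  }

  if (last_breath < n_breaths) {
    gt <- gt[seq_len(last_breath), , drop = FALSE]
    n_samples_kept <- floor(last_breath * cycle / dt)
    agent_ch <- agent_ch[seq_len(n_samples_kept)]
    co2_ch <- co2_ch[seq_len(n_samples_kept)]
    dev_noise <- dev_noise[seq_len(last_breath)]
  }

  if (noise_sd > 0) agent_ch <- agent_ch + stats::rnorm(length(agent_ch), 0, noise_sd)
  if (co2_noise_sd > 0) co2_ch <- co2_ch + stats::rnorm(length(co2_ch), 0, co2_noise_sd)
  # monitor resolution: vol% to 2 decimals, CO2 to 1
  trace <- gas_trace(agent = pmax(round(agent_ch, 2), 0),
                     co2 = pmax(round(co2_ch, 1), 0),
                     sample_period = dt)

  device_log <- data.frame(
    breath_index = gt$breath_index,
    device_ec_volpct = pmax(gt$lung_volpct + dev_noise, 0),
    reservoir_ml = gt$reservoir_ml,
    target_volpct = gt$target_volpct)

  structure(list(trace = trace, device_log = device_log, ground_truth = gt,
                 status = status, etco2 = etco2, seed = as.integer(seed),
                 vent = vent, agent = agent, schedule = schedule,
                 reflector = reflector, injector = injector,
                 lung_volume = lung_volume, reservoir_ml = reservoir_ml),
            class = "acd_sim")
}

#' @export
print.acd_sim <- function(x, ...) {
  cat(sprintf("Simulated bench experiment: %s, %d breaths, %d samples, status %s\n",
              x$agent$name, nrow(x$ground_truth), length(x$trace$agent), x$status))
  invisible(x)
}

#' Ground-truth reflection efficiency over a period
#'
#' The bookkeeping counterpart of the consumption-based reflection
#' efficiency: the percentage of exhaled vapour that was not vented
#' (i.e. was resupplied) over the period. At steady state this equals the
#' value the analysis pipeline derives from liquid consumption.
#'
#' @param sim An `acd_sim` object (or its `ground_truth` data.frame).
#' @param period Length-2 numeric `c(t0, t1)` in seconds; breaths starting
#'   in `[t0, t1)` are included. Default: the whole run.
#' @return Reflection efficiency in percent.
#' @export
steady_state_true_re <- function(sim, period = NULL) {
  gt <- if (inherits(sim, "acd_sim")) sim$ground_truth else sim
  stopifnot(is.data.frame(gt), all(c("vented_ml", "exhaled_ml") %in% names(gt)))
  if (!is.null(period)) {
    stopifnot(length(period) == 2)
    gt <- gt[gt$t_start >= period[1] & gt$t_start < period[2], , drop = FALSE]
  }
  exhaled <- sum(gt$exhaled_ml)
  if (exhaled <= 0)
    stop("no vapour was exhaled in the period: ground-truth reflection efficiency is undefined")
  100 * (1 - sum(gt$vented_ml) / exhaled)
}
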