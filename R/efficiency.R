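#' Liquid anaesthetic consumption per constant-target period
#'
#' Consumption over each period is the drop of the reservoir level between
#' the period boundaries, extrapolated to an hourly rate. The reservoir
#' level "at" a boundary is the last logged value before it (the initial
#' fill for the first period).
#'
#' @param reservoir_ml Per-breath reservoir levels (mL liquid).
#' @param t_breath Times of the logged values, seconds from recording start.
#' @param periods A data.frame with columns `t_start`, `t_end` (seconds),
#'   e.g. a [target_schedule()].
#' @param initial_ml Reservoir level before the first breath; defaults to
#'   the first logged value.
#' @param tolerance Allowed upward reservoir jitter in mL before the series
#'   is rejected as a data error.
#' @return A data.frame, one row per period: `t_start`, `t_end`,
#'   `duration_s`, `liquid_consumed_ml`, `hourly_rate_ml_h`.
#' @examples
#' consumption_per_period(c(250, 249.85, 249.7), c(0, 200, 400),
#'                        data.frame(t_start = 0, t_end = 600))
#' @export
consumption_per_period <- function(reservoir_ml, t_breath, periods,
                                   initial_ml = NULL, tolerance = 1e-6) {
  stopifnot(is.numeric(reservoir_ml), is.numeric(t_breath),
            length(reservoir_ml) == length(t_breath),
            is.data.frame(periods), all(c("t_start", "t_end") %in% names(periods)))
  if (length(reservoir_ml) == 0) stop("empty reservoir series")
  if (is.unsorted(t_breath)) stop("t_breath must be non-decreasing")
  if (any(diff(reservoir_ml) > tolerance))
    stop("reservoir level increases beyond tolerance: data error (the reservoir only empties)")
  if (is.null(initial_ml)) initial_ml <- reservoir_ml[1]
  level_at <- function(t) {
    i <- findInterval(t - 1e-9, t_breath)
    ifelse(i == 0, initial_ml, reservoir_ml[pmax(i, 1)])
  }
  consumed <- pmax(level_at(periods$t_start) - level_at(periods$t_end), 0)
  duration <- periods$t_end - periods$t_start
  data.frame(t_start = periods$t_start, t_end = periods$t_end,
             duration_s = duration,
             liquid_consumed_ml = consumed,
             hourly_rate_ml_h = consumed * 3600 / duration)
}

#' Reflection efficiency from liquid consumption
#'
#' The percentage of exhaled anaesthetic vapour resupplied to the patient,
#' derived at steady state from the hourly liquid infusion (consumption)
#' rate:
#' \deqn{RE [\%] = 100 (1 - 100 \cdot IR \cdot F / (60 \cdot EC \cdot VT \cdot RR))}
#' where IR is in mL liquid/h, F converts mL liquid to mL vapour, EC is the
#' end-tidal concentration in vol%, VT the tidal volume in mL and RR the
#' respiratory rate in breaths/min. Values can be negative when more vapour
#' is delivered than an open system would need (reflector overload).
#'
#' @param ir Hourly liquid consumption, mL/h.
#' @param f Liquid-to-vapour factor, mL vapour per mL liquid.
#' @param ec End-tidal concentration, vol% (> 0).
#' @param vt Tidal volume, mL.
#' @param rr Respiratory rate, breaths/min.
#' @return Reflection efficiency in percent (at most 100).
#' @examples
#' reflection_efficiency(4, 200, 0.4, 500, 10)    # 33.33
#' reflection_efficiency(43, 193, 2.6, 500, 10)   # -6.40: reflector overload
#' @export
reflection_efficiency <- function(ir, f, ec, vt, rr) {
  if (any(vt <= 0) || any(rr <= 0) || any(f <= 0))
    stop("f, vt and rr must be positive")
  if (any(ec <= 0, na.rm = TRUE))
    stop("reflection efficiency requires EC > 0: it is defined from steady-state consumption relative to the vapour in the exhaled breath")
  100 * (1 - (100 * ir * f / (60 * ec * vt * rr)))
}

#' Per-period efficiency table for one experiment
#'
#' Joins the per-breath trace evaluation with the device log over the
#' target schedule: per constant-target period, the mean end-tidal
#' concentration, the liquid consumed and its hourly rate, the vapour
#' volume per exhaled breath (EC/100 x VT) and the reflection efficiency.
#' A drift diagnostic (the absolute difference between the mean EC of the
#' last and first fifth of the period's breaths) is reported because
#' consumption is measured during the staircase, not at verified steady
#' state. Periods below `low_target_mac` MAC are flagged; the flag is meant
#' for excluding widely scattered low-target values from reflection
#' efficiency summaries, never for dropping raw rows.
#'
#' @param breaths A `breath_records` data.frame from [analyze_breaths()].
#' @param device_log Device log with `reservoir_ml` per breath (and
#'   optionally `device_ec_volpct`).
#' @param schedule A [target_schedule()].
#' @param vent A [vent_settings()].
#' @param agent An [agent_spec()].
#' @param sample_period Trace sampling interval in s (to place breaths in
#'   time), default 0.1.
#' @param low_target_mac Periods with target below this MAC fraction are
#'   flagged `low_target` (default 0.6).
#' @param initial_reservoir_ml Reservoir fill before the first breath;
#'   defaults to the first logged level (which then misses any consumption
#'   within the very first breath).
#' @return A data.frame of class `efficiency_records`, one row per period.
#' @export
efficiency_table <- function(breaths, device_log, schedule, vent, agent,
                             sample_period = 0.1, low_target_mac = 0.6,
                             initial_reservoir_ml = NULL) {
  stopifnot(inherits(schedule, "target_schedule"), inherits(vent, "vent_settings"),
            inherits(agent, "agent_spec"))
  onset_s <- breaths$expiration_onset_ms / 1000
  period_idx <- findInterval(onset_s, schedule$t_start)
  period_idx[onset_s >= schedule$t_end[nrow(schedule)]] <- nrow(schedule)
  cycle <- 60 / vent$respiratory_rate
  breath_t <- (device_log$breath_index - 1) * cycle
  cons <- consumption_per_period(device_log$reservoir_ml, breath_t, schedule,
                                 initial_ml = initial_reservoir_ml)

  per_period <- function(p) {
    ec <- breaths$ec_volpct[period_idx == p]
    ec <- ec[!is.na(ec)]
    n5 <- max(1L, floor(length(ec) / 5))
    drift <- if (length(ec) >= 2) {
      abs(mean(ec[seq(length(ec) - n5 + 1, length(ec))]) - mean(ec[seq_len(n5)]))
    } else NA_real_
    c(mean_ec = if (length(ec)) mean(ec) else NA_real_,
      n_breaths = length(ec), ec_drift = drift)
  }
  ecs <- t(vapply(seq_len(nrow(schedule)), per_period, numeric(3)))

  out <- data.frame(
    period = seq_len(nrow(schedule)),
    target_mac = schedule$fraction,
    target_volpct = mac_to_volpct(schedule$fraction, agent),
    mean_ec = ecs[, "mean_ec"],
    n_breaths = as.integer(ecs[, "n_breaths"]),
    period_duration_s = cons$duration_s,
    liquid_consumed_ml = cons$liquid_consumed_ml,
    hourly_rate_ml_h = cons$hourly_rate_ml_h,
    ec_drift = ecs[, "ec_drift"])
  out$vapour_per_breath_ml <- out$mean_ec / 100 * vent$tidal_volume
  out$re_percent <- ifelse(
    !is.na(out$mean_ec) & out$mean_ec > 0,
    100 * (1 - (100 * out$hourly_rate_ml_h * agent$vapour_factor_f /
                  (60 * out$mean_ec * vent$tidal_volume * vent$respiratory_rate))),
    NA_real_)
  out$low_target <- schedule$fraction < low_target_mac
  structure(out, class = c("efficiency_records", "data.frame"),
            vent = vent, agent = agent)
}

#' Average ascending and descending occurrences of each target
#'
#' The staircase visits every ordinary target twice (wash-in and wash-out);
#' averaging the two consumption rates and mean end-tidal concentrations
#' cancels the wash-in/wash-out bias. The peak target occurs once and
#' passes through unchanged. Vapour volume per breath and reflection
#' efficiency are recomputed from the averaged values.
#'
#' @param records An `efficiency_records` table from [efficiency_table()].
#' @return A data.frame, one row per distinct target level, ordered by
#'   target; column `n_periods` gives the number of periods averaged.
#' @export
average_up_down <- function(records) {
  stopifnot(inherits(records, "efficiency_records"))
  if (nrow(records) == 0) stop("no efficiency records to average")
  vent <- attr(records, "vent"); agent <- attr(records, "agent")
  key <- round(records$target_volpct, 6)
  levels <- sort(unique(key))
  rows <- lapply(levels, function(lv) {
    r <- records[key == lv, , drop = FALSE]
    if (nrow(r) > 2)
      warning(sprintf("target %g vol%% occurs %d times; averaging all", lv, nrow(r)))
    data.frame(target_mac = r$target_mac[1], target_volpct = r$target_volpct[1],
               n_periods = nrow(r),
               mean_ec = mean(r$mean_ec, na.rm = TRUE),
               hourly_rate_ml_h = mean(r$hourly_rate_ml_h),
               low_target = r$low_target[1])
  })
  out <- do.call(rbind, rows)
  out$vapour_per_breath_ml <- out$mean_ec / 100 * vent$tidal_volume
  out$re_percent <- ifelse(
    !is.na(out$mean_ec) & out$mean_ec > 0,
    100 * (1 - (100 * out$hourly_rate_ml_h * agent$vapour_factor_f /
                  (60 * out$mean_ec * vent$tidal_volume * vent$respiratory_rate))),
    NA_real_)
  structure(out, class = c("efficiency_records", "data.frame"),
            vent = vent, agent = agent)
}

#' Greenhouse-gas savings of a consumption reduction
#'
#' Converts a reduction of the hourly liquid consumption into CO2
#' equivalents: `delta_ir x density x gwp x hours`. The liquid density is a
#' required explicit argument, not a hidden constant.
#'
#' @param delta_ir Consumption reduction in mL liquid/h.
#' @param density Liquid density in g/mL.
#' @param gwp Global-warming potential in kg CO2e per g of agent.
#' @param hours Duration in hours.
#' @return Savings in kg CO2 equivalents.
#' @examples
#' co2e_savings(2, 1.50, 1.9, 24)  # 136.8 kg per patient day
#' @export
co2e_savings <- function(delta_ir, density, gwp, hours) {
  if (any(c(delta_ir, density, gwp, hours) < 0))
    stop("all inputs must be non-negative")
  delta_ir * density * gwp * hours
}
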