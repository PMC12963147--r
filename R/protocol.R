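#' Ventilation settings for volume-controlled ventilation
#'
#' Bundles the ventilator configuration used on the bench: volume-controlled
#' ventilation with constant inspiratory flow, a fixed inspiration:expiration
#' ratio and an inspiratory pause filling whatever part of inspiration the
#' flow does not use.
#'
#' @param tidal_volume Tidal volume VT in mL.
#' @param respiratory_rate Respiratory rate RR in breaths/min.
#' @param ie_ratio Inspiration:expiration ratio as a length-2 numeric vector
#'   of positive parts, default `c(1, 1)`.
#' @param inspiratory_flow Constant inspiratory flow in L/min. Together with
#'   VT this fixes the inspiratory-flow time `VT / flow`.
#' @param peep Positive end-expiratory pressure in hPa (informational).
#' @param fio2 Inspired oxygen fraction (informational).
#'
#' @return An object of class `vent_settings`.
#' @seealso [phase_durations()]
#' @examples
#' vent_settings()                          # 500 mL, 10/min, 12 L/min
#' vent_settings(inspiratory_flow = 60)     # short 0.5 s inspiratory-flow time
#' @export
vent_settings <- function(tidal_volume = 500,
                          respiratory_rate = 10,
                          ie_ratio = c(1, 1),
                          inspiratory_flow = 12,
                          peep = 3,
                          fio2 = 0.21) {
  stopifnot(is.numeric(tidal_volume), length(tidal_volume) == 1,
            is.numeric(respiratory_rate), length(respiratory_rate) == 1,
            is.numeric(inspiratory_flow), length(inspiratory_flow) == 1,
            is.numeric(ie_ratio), length(ie_ratio) == 2)
  if (tidal_volume <= 0) stop("tidal_volume must be positive (mL)")
  if (respiratory_rate <= 0) stop("respiratory_rate must be positive (breaths/min)")
  if (inspiratory_flow <= 0) stop("inspiratory_flow must be positive (L/min)")
  if (any(ie_ratio <= 0)) stop("both parts of ie_ratio must be positive")
  v <- structure(
    list(tidal_volume = tidal_volume,
         respiratory_rate = respiratory_rate,
         ie_ratio = ie_ratio,
         inspiratory_flow = inspiratory_flow,
         peep = peep,
         fio2 = fio2),
    class = "vent_settings")
  phase_durations(v)  # errors if flow time does not fit into inspiration
  v
}

#' @export
print.vent_settings <- function(x, ...) {
  ph <- phase_durations(x)
  cat(sprintf(
    "Volume-controlled ventilation: VT %g mL, RR %g/min, I:E %g:%g, flow %g L/min\n",
    x$tidal_volume, x$respiratory_rate, x$ie_ratio[1], x$ie_ratio[2],
    x$inspiratory_flow))
  cat(sprintf("  phases: flow %.2f s, pause %.2f s, expiration %.2f s\n",
              ph[["flow_time"]], ph[["pause_time"]], ph[["expiration_time"]]))
  invisible(x)
}

#' Breath phase durations implied by the ventilator settings
#'
#' With constant-flow volume control the inspiratory-flow time is
#' `VT / inspiratory_flow`; the rest of the inspiration is an inspiratory
#' pause, and expiration fills the remainder of the cycle `60 / RR`
#' according to the I:E ratio.
#'
#' @param v A [vent_settings()] object.
#' @return Named numeric vector `c(flow_time, pause_time, expiration_time)`
#'   in seconds; the three sum to the breath cycle `60 / RR`.
#' @examples
#' phase_durations(vent_settings())  # 2.5, 0.5, 3.0
#' @export
phase_durations <- function(v) {
  stopifnot(inherits(v, "vent_settings") || is.list(v))
  cycle <- 60 / v$respiratory_rate
  inspiration <- cycle * v$ie_ratio[1] / sum(v$ie_ratio)
  flow_time <- v$tidal_volume / (v$inspiratory_flow * 1000 / 60)
  if (flow_time > inspiration + 1e-9) {
    stop(sprintf(
      "inspiratory-flow time %.2f s exceeds the %.2f s inspiration: the pause would be negative",
      flow_time, inspiration))
  }
  c(flow_time = flow_time,
    pause_time = inspiration - flow_time,
    expiration_time = cycle - inspiration)
}

#' Anaesthetic agent specification
#'
#' Identity, MAC reference and liquid-to-vapour conversion factor of the
#' volatile agent. The MAC references are the concentrations the delivery
#' device assumes equal to 1.0 MAC for a 40-year-old: 1.2 vol% for
#' isoflurane and 1.9 vol% for sevoflurane. The vapour factor F is the mL of
#' vapour produced per mL of liquid agent (isoflurane 200, sevoflurane 193).
#'
#' @param name `"isoflurane"` or `"sevoflurane"`.
#' @param mac_volpct Concentration (vol%) equal to 1.0 MAC; defaults per agent.
#' @param vapour_factor_f mL vapour per mL liquid; defaults per agent.
#' @return An object of class `agent_spec`.
#' @examples
#' agent_spec("isoflurane")
#' agent_spec("sevoflurane")
#' @export
agent_spec <- function(name = c("isoflurane", "sevoflurane"),
                       mac_volpct = NULL,
                       vapour_factor_f = NULL) {
  name <- match.arg(name)
  defaults <- list(isoflurane  = list(mac = 1.2, f = 200),
                   sevoflurane = list(mac = 1.9, f = 193))[[name]]
  if (is.null(mac_volpct)) mac_volpct <- defaults$mac
  if (is.null(vapour_factor_f)) vapour_factor_f <- defaults$f
  if (mac_volpct <= 0) stop("mac_volpct must be positive (vol%)")
  if (vapour_factor_f <= 0) stop("vapour_factor_f must be positive (mL vapour / mL liquid)")
  structure(list(name = name,
                 mac_volpct = mac_volpct,
                 vapour_factor_f = vapour_factor_f),
            class = "agent_spec")
}

#' Convert a MAC fraction to a target concentration in vol%
#'
#' @param fraction MAC multiple (>= 0), e.g. 1.5 for 1.5 MAC.
#' @param agent An [agent_spec()].
#' @return Target concentration in vol%.
#' @examples
#' mac_to_volpct(1.5, agent_spec("sevoflurane"))  # 2.85
#' mac_to_volpct(1.4, agent_spec("isoflurane"))   # 1.68
#' @export
mac_to_volpct <- function(fraction, agent) {
  stopifnot(inherits(agent, "agent_spec"), is.numeric(fraction))
  if (any(fraction < 0)) stop("MAC fraction must be non-negative")
  fraction * agent$mac_volpct
}

#' Target schedule of MAC fractions
#'
#' An ordered sequence of constant-target periods, each a MAC fraction held
#' for a duration in seconds.
#'
#' @param fractions Numeric vector of MAC multiples (>= 0).
#' @param durations Numeric vector of period durations in seconds (> 0),
#'   recycled to `length(fractions)` if scalar.
#' @return An object of class `target_schedule`: a data.frame with columns
#'   `fraction`, `duration`, `t_start`, `t_end` (seconds from recording start).
#' @seealso [staircase_schedule()]
#' @export
target_schedule <- function(fractions, durations) {
  stopifnot(is.numeric(fractions), is.numeric(durations))
  if (length(durations) == 1) durations <- rep(durations, length(fractions))
  if (length(durations) != length(fractions))
    stop("fractions and durations must have equal length")
  if (any(durations <= 0)) stop("all period durations must be positive")
  if (any(fractions < 0)) stop("MAC fractions must be non-negative")
  t_end <- cumsum(durations)
  structure(
    data.frame(fraction = fractions,
               duration = durations,
               t_start = t_end - durations,
               t_end = t_end),
    class = c("target_schedule", "data.frame"))
}

#' Total duration of a schedule in seconds
#' @param schedule A [target_schedule()].
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "target_schedule"))
  sum(schedule$duration)
}

#' The staircase target schedule of the bench protocol
#'
#' Ascending steps from `step` up to `max_fraction - step` in increments of
#' `step`, each held `step_duration` seconds, then the peak `max_fraction`
#' held `peak_duration` seconds, then the mirror-image descent. Recording
#' ends when the terminal 0.0 target is set, so the 0.0 step contributes no
#' recorded period. With the defaults this gives 15 periods
#' (0.2...1.4 up, 1.5 for 20 min, 1.4...0.2 down) totalling 160 min.
#'
#' @param max_fraction Peak MAC multiple (default 1.5).
#' @param step Staircase increment in MAC (default 0.2).
#' @param step_duration Seconds per ordinary step (default 600).
#' @param peak_duration Seconds at the peak (default 1200).
#' @return A [target_schedule()].
#' @examples
#' sched <- staircase_schedule()
#' nrow(sched)               # 15 periods
#' schedule_duration(sched)  # 9600 s = 160 min
#' @export
staircase_schedule <- function(max_fraction = 1.5, step = 0.2,
                               step_duration = 600, peak_duration = 1200) {
  if (step_duration <= 0 || peak_duration <= 0)
    stop("step_duration and peak_duration must be positive")
  if (step <= 0 || max_fraction <= 0)
    stop("step and max_fraction must be positive")
  # ordinary steps are the multiples of `step` strictly below the peak
  # (the peak itself may sit a fraction of a step above the last one)
  n_below <- floor((max_fraction - 1e-9) / step)
  up <- step * seq_len(n_below)
  fractions <- c(up, max_fraction, rev(up))
  durations <- c(rep(step_duration, n_below), peak_duration,
                 rep(step_duration, n_below))
  target_schedule(fractions, durations)
}

#' Target concentration over time
#'
#' Evaluates the schedule at arbitrary times; times at a period boundary
#' belong to the later period (half-open periods), and times at or past the
#' end of the schedule return 0 (recording ends when the 0.0 target is set).
#'
#' @param schedule A [target_schedule()].
#' @param t Numeric vector of times in seconds from recording start.
#' @param agent Optional [agent_spec()]; if given, returns vol% rather than
#'   MAC fractions.
#' @return Numeric vector of targets (MAC fraction, or vol% with `agent`).
#' @export
schedule_target_at <- function(schedule, t, agent = NULL) {
  stopifnot(inherits(schedule, "target_schedule"), is.numeric(t))
  idx <- findInterval(t, schedule$t_start)
  frac <- ifelse(idx >= 1 & t < schedule$t_end[pmin(idx, nrow(schedule))] & idx <= nrow(schedule),
                 schedule$fraction[pmax(idx, 1)], 0)
  frac[t < 0] <- 0
  if (is.null(agent)) frac else mac_to_volpct(frac, agent)
}
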