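#' Round all numeric columns of a data.frame
#'
#' Convenience for writing derived tables at a fixed documented precision.
#'
#' @param df A data.frame.
#' @param digits Decimal places (default 4).
#' @return The data.frame with numeric columns rounded.
#' @export
round_numeric <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Atomic CSV write
#'
#' Writes to a temporary file in the target directory and renames it into
#' place, so an interrupted run never leaves a truncated CSV.
#'
#' @param df A data.frame.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not move temporary file into place at ", path)
  }
  invisible(path)
}

#' Write a gas trace to CSV
#'
#' Columns: `t_ms` (integer multiples of the sample period), `agent_volpct`
#' (2 decimals), `co2_mmHg` (1 decimal).
#'
#' @param trace A [gas_trace()].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "gas_trace"))
  n <- length(trace$agent)
  agent <- trace$agent; agent[agent == 0] <- 0   # normalise negative zero
  co2 <- trace$co2; co2[co2 == 0] <- 0
  df <- data.frame(t_ms = as.integer(round((seq_len(n) - 1) *
                                             trace$sample_period * 1000)),
                   agent_volpct = sprintf("%.2f", agent),
                   co2_mmHg = sprintf("%.1f", co2))
  write_csv_atomic(df, path)
}

#' Read a gas trace from CSV
#'
#' Validates the trace dialect written by [write_trace()]: required
#' columns, numeric cells and a strictly uniform time base (the sample
#' period is inferred from the `t_ms` spacing).
#'
#' @param path Path to a trace CSV.
#' @return A [gas_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("t_ms", "agent_volpct", "co2_mmHg")
  if (!all(need %in% names(df)))
    stop("trace file is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  num <- lapply(df[need], function(x) suppressWarnings(as.numeric(x)))
  for (col in need) {
    bad <- which(is.na(num[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data line %d of %s",
                   col, bad[1], path))
  }
  t_ms <- num$t_ms
  if (length(t_ms) < 2) stop("trace must contain at least 2 samples")
  steps <- diff(t_ms)
  if (any(steps != steps[1])) {
    g <- which(steps != steps[1])[1]
    stop(sprintf("non-uniform time base: gap between t = %d and t = %d ms (data line %d)",
                 as.integer(t_ms[g]), as.integer(t_ms[g + 1]), g))
  }
  gas_trace(agent = num$agent_volpct, co2 = num$co2_mmHg,
            sample_period = steps[1] / 1000)
}

#' Write / read a per-breath device log
#'
#' Columns: `breath_index`, `device_ec_volpct`, `reservoir_ml`,
#' `target_volpct`.
#'
#' @param device_log A data.frame with the columns above.
#' @param path CSV path.
#' @return Invisibly `path` (writer); the validated data.frame (reader).
#' @export
write_device_log <- function(device_log, path) {
  need <- c("breath_index", "device_ec_volpct", "reservoir_ml", "target_volpct")
  stopifnot(all(need %in% names(device_log)))
  write_csv_atomic(round_numeric(device_log[need], 4), path)
}

#' @rdname write_device_log
#' @export
read_device_log <- function(path) {
  if (!file.exists(path)) stop("device log not found: ", path)
  df <- utils::read.csv(path)
  need <- c("breath_index", "device_ec_volpct", "reservoir_ml", "target_volpct")
  if (!all(need %in% names(df)))
    stop("device log is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Read an experiment configuration file
#'
#' YAML (or JSON) with up to five blocks, all optional, all keys defaulting
#' to the bench protocol:
#' \preformatted{
#' ventilation: {tidal_volume: 500, respiratory_rate: 10, ie_ratio: [1, 1],
#'               inspiratory_flow: 12, peep: 3, fio2: 0.21}
#' agent:       {name: isoflurane, mac_volpct: 1.2, vapour_factor_f: 200}
#' schedule:    {max_fraction: 1.5, step: 0.2, step_duration: 600,
#'               peak_duration: 1200}
#'   # or an explicit list:  steps: [{fraction: 0.5, duration: 600}, ...]
#' reflector:   {base_efficiency: 0.85, capacity_per_breath: 12, ...}
#' injector:    {vapour_rate: 2.5, gain: 1.0, trigger_hysteresis: 0.1, ...}
#' simulation:  {noise_sd: 0.01, reservoir_ml: 250, ...}
#' }
#'
#' @param path Path to the config file, or a pre-parsed list.
#' @return A list with elements `vent`, `agent`, `schedule`, `reflector`,
#'   `injector`, `simulation` (a plain list of extra simulator arguments).
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  take <- function(block, builder) do.call(builder, cfg[[block]] %||% list())
  vent <- take("ventilation", vent_settings)
  agent <- take("agent", agent_spec)
  sb <- cfg$schedule %||% list()
  schedule <- if (!is.null(sb$steps)) {
    target_schedule(vapply(sb$steps, `[[`, numeric(1), "fraction"),
                    vapply(sb$steps, `[[`, numeric(1), "duration"))
  } else do.call(staircase_schedule, sb)
  list(vent = vent, agent = agent, schedule = schedule,
       reflector = take("reflector", reflector_params),
       injector = take("injector", injector_params),
       simulation = cfg$simulation %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulate-analyse-report pipeline
#'
#' Simulates one experiment under the configuration, evaluates the trace
#' breath by breath, computes the per-period and per-target efficiency
#' tables, the device-vs-monitor agreement, and renders the report bundle
#' into `outdir` together with a run manifest. Re-running with the same
#' configuration and seed reproduces all stochastic outputs bit-identically
#' (manifests differ only in their timestamp).
#'
#' @param config Path to a configuration file (see [read_config()]) or a
#'   pre-parsed configuration list.
#' @param seed Integer seed for the simulation.
#' @param outdir Output directory.
#' @param formats Report formats, subset of `c("csv", "png")`.
#' @return Invisibly, a list with the in-memory results: `sim`, `breaths`,
#'   `efficiency`, `averaged`, `agreement`, `manifest`.
#' @export
run_pipeline <- function(config, seed, outdir, formats = c("csv", "png")) {
  cfg <- read_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  message("stage simulate: ", cfg$agent$name, ", ",
          nrow(cfg$schedule), " target periods")
  sim <- do.call(simulate_experiment,
                 c(list(vent = cfg$vent, agent = cfg$agent,
                        schedule = cfg$schedule, reflector = cfg$reflector,
                        injector = cfg$injector, seed = seed),
                   cfg$simulation))
  if (sim$status != "completed")
    warning("simulation ended early: ", sim$status)
  write_trace(sim$trace, file.path(outdir, "trace.csv"))
  write_device_log(sim$device_log, file.path(outdir, "device_log.csv"))

  message("stage analyze breaths")
  breaths <- analyze_breaths(sim$trace)
  write_csv_atomic(round_numeric(breaths, 4), file.path(outdir, "breaths.csv"))

  message("stage analyze efficiency")
  eff <- efficiency_table(breaths, sim$device_log, cfg$schedule, cfg$vent,
                          cfg$agent, initial_reservoir_ml = sim$reservoir_ml)
  avg <- average_up_down(eff)

  message("stage stats")
  n <- min(nrow(breaths), nrow(sim$device_log))
  agreement <- bland_altman(sim$device_log$device_ec_volpct[seq_len(n)],
                            breaths$ec_volpct[seq_len(n)])

  message("stage report")
  render_report(outdir, breaths = breaths, device_log = sim$device_log,
                schedule = cfg$schedule, vent = cfg$vent, agent = cfg$agent,
                agreement = agreement, efficiency = eff, averaged = avg,
                formats = formats)

  manifest <- list(
    tool = "acdbench",
    version = as.character(utils::packageVersion("acdbench")),
    seed = as.integer(seed),
    config_digest = config_digest(if (is.list(config)) config else yaml::read_yaml(config)),
    status = sim$status,
    n_breaths = nrow(sim$ground_truth),
    n_samples = length(sim$trace$agent),
    outputs = sort(basename(list.files(outdir))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  tmp <- tempfile(tmpdir = outdir, fileext = ".json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.rename(tmp, file.path(outdir, "manifest.json"))

  invisible(list(sim = sim, breaths = breaths, efficiency = eff,
                 averaged = avg, agreement = agreement, manifest = manifest))
}

#' @keywords internal
config_digest <- function(cfg) {
  canon <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # small stable checksum without extra dependencies
  bytes <- as.integer(charToRaw(as.character(canon)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("djb2-%d-%d", length(bytes), h)
}
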