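#' Dual-channel gas trace
#'
#' A uniformly sampled side-stream monitor recording: anaesthetic agent in
#' vol% and CO2 in mmHg. Sample `i` (1-based) covers the time interval
#' `[(i-1) * sample_period, i * sample_period)`.
#'
#' @param agent Numeric vector, agent concentration in vol%.
#' @param co2 Numeric vector (same length), CO2 partial pressure in mmHg.
#' @param sample_period Sampling interval in seconds (default 0.1).
#' @return An object of class `gas_trace`.
#' @export
gas_trace <- function(agent, co2, sample_period = 0.1) {
  stopifnot(is.numeric(agent), is.numeric(co2))
  if (length(agent) != length(co2))
    stop("agent and co2 channels must have equal length")
  if (sample_period <= 0) stop("sample_period must be positive")
  if (anyNA(agent) || anyNA(co2))
    stop("gas traces must not contain missing samples (gaps are an input error)")
  structure(list(agent = as.numeric(agent), co2 = as.numeric(co2),
                 sample_period = sample_period),
            class = "gas_trace")
}

#' @export
print.gas_trace <- function(x, ...) {
  cat(sprintf("gas_trace: %d samples at %g s (%.1f s)\n",
              length(x$agent), x$sample_period,
              length(x$agent) * x$sample_period))
  invisible(x)
}

#' @export
length.gas_trace <- function(x) length(x$agent)

#' Segment breaths by supra-threshold CO2 runs
#'
#' Marks all CO2 samples exceeding the threshold to roughly identify
#' expiration, and returns the maximal contiguous runs. Runs shorter than
#' the debounce length are discarded as noise. Samples exactly at the
#' threshold are sub-threshold (strict inequality).
#'
#' @param trace A [gas_trace()].
#' @param co2_threshold Threshold in mmHg (default 34).
#' @param debounce_s Minimum run duration in seconds (default 0.5).
#' @return A data.frame with one row per run: `breath_index`, `start`,
#'   `end` (1-based inclusive sample indices), `n_samples`.
#' @export
segment_breaths <- function(trace, co2_threshold = 34, debounce_s = 0.5) {
  stopifnot(inherits(trace, "gas_trace"))
  if (co2_threshold <= 0) stop("co2_threshold must be positive (mmHg)")
  n <- length(trace$co2)
  empty <- data.frame(breath_index = integer(), start = integer(),
                      end = integer(), n_samples = integer())
  if (n == 0) return(empty)
  r <- rle(trace$co2 > co2_threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= max(1L, round(debounce_s / trace$sample_period))
  if (!any(keep)) return(empty)
  data.frame(breath_index = seq_len(sum(keep)),
             start = starts[keep], end = ends[keep],
             n_samples = r$lengths[keep])
}

#' End-tidal anaesthetic concentration of one breath
#'
#' Averages a fixed window of agent samples beginning a fixed offset after
#' the first supra-threshold CO2 sample of the breath. The offset skips the
#' rising edge; the fixed window stops before expired gas retained in the
#' interface reaches the port during early inspiration, where injection
#' peaks would contaminate the average.
#'
#' @param trace A [gas_trace()].
#' @param run One row of [segment_breaths()] output (or a list with `start`).
#' @param offset Offset in seconds after the run start (default 0.2).
#' @param window Number of agent samples averaged (default 20).
#' @return The end-tidal concentration in vol%, or `NA` (with a warning) if
#'   the run is too short to supply `offset + window` samples.
#' @export
compute_ec <- function(trace, run, offset = 0.2, window = 20) {
  stopifnot(inherits(trace, "gas_trace"))
  off_n <- round(offset / trace$sample_period)
  need <- off_n + window
  if (run$n_samples < need) {
    warning(sprintf(
      "breath run of %d samples is shorter than the %d needed (offset + window): EC marked missing",
      run$n_samples, need))
    return(NA_real_)
  }
  i0 <- run$start + off_n
  mean(trace$agent[i0:(i0 + window - 1)])
}

#' Indices of the samples entering an end-tidal average
#'
#' Exposes the exact averaging window of [compute_ec()] for inspection and
#' plotting; `compute_ec` is `mean(trace$agent[ec_window_indices(...)])`.
#'
#' @inheritParams compute_ec
#' @return Integer vector of 1-based sample indices (empty if the run is
#'   too short).
#' @export
ec_window_indices <- function(trace, run, offset = 0.2, window = 20) {
  stopifnot(inherits(trace, "gas_trace"))
  off_n <- round(offset / trace$sample_period)
  if (run$n_samples < off_n + window) return(integer())
  (run$start + off_n):(run$start + off_n + window - 1L)
}

#' Quantify the inspiratory injection peak of one breath
#'
#' Over the inspiratory window (the samples between the end of this
#' breath's expiration run and the start of the next run), the end-tidal
#' concentration of the subsequent breath is subtracted from the real-time
#' agent samples. The count of positive excess samples divided by the
#' sample rate gives the injection time; their sum divided by the sample
#' rate gives the area under the peak.
#'
#' @param trace A [gas_trace()].
#' @param window_start,window_end 1-based inclusive sample indices of the
#'   inspiratory window; an empty window (`window_end < window_start`)
#'   yields no peak.
#' @param next_ec End-tidal concentration of the subsequent breath (vol%).
#' @param min_samples Minimum positive-excess samples for a peak (default 2).
#' @param min_excess Minimum `cpeak - next_ec` in vol% for a peak
#'   (default 0.05); together with `min_samples` this gates out noise-only
#'   "peaks".
#' @return A list: `cpeak` (max agent in the window, vol%), `t_inj` (s),
#'   `auc` (vol%.s), `peak_present` (logical).
#' @export
quantify_peak <- function(trace, window_start, window_end, next_ec,
                          min_samples = 2, min_excess = 0.05) {
  stopifnot(inherits(trace, "gas_trace"))
  if (is.na(next_ec) || window_end < window_start)
    return(list(cpeak = NA_real_, t_inj = 0, auc = 0, peak_present = FALSE))
  seg <- trace$agent[window_start:window_end]
  excess <- seg - next_ec
  pos <- excess[excess > 0]
  per_s <- 1 / trace$sample_period          # samples per second (10 at 100 ms)
  t_inj <- length(pos) / per_s
  auc <- sum(pos) / per_s
  cpeak <- max(seg)
  list(cpeak = cpeak, t_inj = t_inj, auc = auc,
       peak_present = length(pos) >= min_samples && (cpeak - next_ec) >= min_excess)
}

#' Breath-by-breath evaluation of a gas trace
#'
#' Runs the full trace evaluation: expiration marking by supra-threshold
#' CO2, end-tidal extraction per breath, and injection-peak quantification
#' over each inter-run inspiratory window. The final breath has no
#' subsequent end-tidal value, so its peak is quantified against its own;
#' breaths too short for the averaging window keep `NA` end-tidal values
#' and are excluded from downstream means.
#'
#' @param trace A [gas_trace()].
#' @param co2_threshold mmHg, see [segment_breaths()].
#' @param offset,window See [compute_ec()].
#' @param min_samples,min_excess See [quantify_peak()].
#' @param debounce_s See [segment_breaths()].
#' @return A data.frame of class `breath_records`, one row per breath:
#'   `breath_index`, `expiration_onset` (sample index), `expiration_onset_ms`,
#'   `ec_volpct`, `cpeak_volpct`, `t_inj_s`, `auc_volpcts`, `peak_present`.
#' @export
analyze_breaths <- function(trace, co2_threshold = 34, offset = 0.2,
                            window = 20, min_samples = 2, min_excess = 0.05,
                            debounce_s = 0.5) {
  runs <- segment_breaths(trace, co2_threshold, debounce_s)
  n <- nrow(runs)
  out <- data.frame(breath_index = integer(n), expiration_onset = integer(n),
                    expiration_onset_ms = integer(n), ec_volpct = NA_real_,
                    cpeak_volpct = NA_real_, t_inj_s = 0, auc_volpcts = 0,
                    peak_present = logical(n))
  if (n == 0) return(structure(out, class = c("breath_records", "data.frame")))
  ecs <- vapply(seq_len(n), function(i) compute_ec(trace, runs[i, ], offset, window),
                numeric(1))
  n_missing <- sum(is.na(ecs))
  if (n_missing > 0)
    message(sprintf("analyze_breaths: %d of %d breaths incomplete (EC missing)",
                    n_missing, n))
  for (i in seq_len(n)) {
    ws <- runs$end[i] + 1L
    we <- if (i < n) runs$start[i + 1L] - 1L else length(trace$agent)
    next_ec <- if (i < n) ecs[i + 1L] else ecs[i]
    pk <- quantify_peak(trace, ws, we, next_ec, min_samples, min_excess)
    out$breath_index[i] <- i
    out$expiration_onset[i] <- runs$start[i]
    out$expiration_onset_ms[i] <- as.integer(round((runs$start[i] - 1L) *
                                                     trace$sample_period * 1000))
    out$ec_volpct[i] <- ecs[i]
    out$cpeak_volpct[i] <- pk$cpeak
    out$t_inj_s[i] <- pk$t_inj
    out$auc_volpcts[i] <- pk$auc
    out$peak_present[i] <- pk$peak_present
  }
  structure(out, class = c("breath_records", "data.frame"))
}
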