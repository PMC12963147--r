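#!/usr/bin/env Rscript
# Breath-by-breath evaluation of the simulated traces: expiration marking at
# CO2 > 34 mmHg, end-tidal extraction (20 samples from 0.2 s after onset)
# and injection-peak quantification. Expects analysis/01_simulate.R to have
# populated scratch/runs/.

library(acdbench)

experiments <- list.dirs("scratch/runs", recursive = FALSE)
if (length(experiments) == 0) stop("run analysis/01_simulate.R first")

rows <- list()
for (dir in experiments) {
  name <- basename(dir)
  trace <- read_trace(file.path(dir, "trace.csv"))
  br <- analyze_breaths(trace)
  write_csv_atomic(round_numeric(br, 4), file.path(dir, "breaths.csv"))
  pk <- br[br$peak_present, ]
  rows[[name]] <- data.frame(
    experiment = name,
    n_breaths = nrow(br),
    n_ec_missing = sum(is.na(br$ec_volpct)),
    n_peaks = nrow(pk),
    t_inj_min_s = min(pk$t_inj_s), t_inj_max_s = max(pk$t_inj_s),
    auc_min = min(pk$auc_volpcts), auc_max = max(pk$auc_volpcts),
    auc_mean = mean(pk$auc_volpcts))
  cat(sprintf(
    "%s: %d breaths (%d EC missing), %d injection peaks, t_inj %.1f-%.1f s, AUC %.1f-%.1f (mean %.1f) vol%%.s\n",
    name, nrow(br), rows[[name]]$n_ec_missing, nrow(pk),
    min(pk$t_inj_s), max(pk$t_inj_s),
    min(pk$auc_volpcts), max(pk$auc_volpcts), mean(pk$auc_volpcts)))
}

write_csv_atomic(round_numeric(do.call(rbind, rows), 3), "results/02_breaths_summary.csv")
cat("wrote results/02_breaths_summary.csv\n")
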