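#!/usr/bin/env Rscript
# Agreement between the device's per-breath end-tidal values and the
# external monitor's trace-derived values, per experiment (Bland-Altman).

library(acdbench)

experiments <- list.dirs("scratch/runs", recursive = FALSE)
if (length(experiments) == 0) stop("run analysis/01_simulate.R first")

rows <- list()
for (dir in experiments) {
  name <- basename(dir)
  br <- utils::read.csv(file.path(dir, "breaths.csv"))
  dl <- read_device_log(file.path(dir, "device_log.csv"))
  n <- min(nrow(br), nrow(dl))
  ba <- bland_altman(dl$device_ec_volpct[seq_len(n)], br$ec_volpct[seq_len(n)])
  rows[[name]] <- data.frame(experiment = name, n = ba$n,
                             bias_volpct = ba$bias, sd_diff = ba$sd_diff,
                             loa_low = ba$loa_low, loa_high = ba$loa_high)
  cat(sprintf("%s: bias %+.4f vol%%, limits of agreement [%.4f, %.4f] (n = %d)\n",
              name, ba$bias, ba$loa_low, ba$loa_high, ba$n))
}

write_csv_atomic(round_numeric(do.call(rbind, rows), 4), "results/04_agreement.csv")
cat("wrote results/04_agreement.csv\n")
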