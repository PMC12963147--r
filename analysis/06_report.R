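#!/usr/bin/env Rscript
# Render the figure/table bundle for one experiment end to end through the
# packaged pipeline (time course, agreement, efficiency); writes the bundle
# (per-breath CSVs plus PNG figures) to scratch/report_iso_long/.

library(acdbench)

dir <- "scratch/runs/iso_long"
if (!dir.exists(dir)) stop("run analysis/01_simulate.R first")

schedule <- staircase_schedule()
vent <- vent_settings()
agent <- agent_spec("isoflurane")
trace <- read_trace(file.path(dir, "trace.csv"))
br <- analyze_breaths(trace)
dl <- read_device_log(file.path(dir, "device_log.csv"))
eff <- efficiency_table(br, dl, schedule, vent, agent)
avg <- average_up_down(eff)
n <- min(nrow(br), nrow(dl))
ba <- bland_altman(dl$device_ec_volpct[seq_len(n)], br$ec_volpct[seq_len(n)])

paths <- render_report("scratch/report_iso_long", breaths = br, device_log = dl,
                       schedule = schedule, vent = vent, agent = agent,
                       agreement = ba, efficiency = eff, averaged = avg)
cat("report files:\n")
cat(paste0("  ", paths, collapse = "\n"), "\n")
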