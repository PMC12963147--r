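#!/usr/bin/env Rscript
# Consumption-vs-concentration regression across the four experiments:
# per-experiment degree-2 polynomial fits, ventilation-mode contrasts per
# agent, and the agent-vs-agent contrast at the short flow time with the
# three highest sevoflurane targets excluded (their disproportionate
# consumption would dominate the comparison). Also tabulates reflection
# efficiency over vapour volume per exhaled breath (low targets flagged
# out, as their 10-minute consumption scatters widely).

library(acdbench)

targets <- utils::read.csv("results/03_targets.csv")
targets$group <- targets$experiment

fit_all <- fit_consumption(targets)
sevo_top3 <- sort(unique(targets$target_volpct[grepl("sevo", targets$group)]),
                  decreasing = TRUE)[1:3]
excl <- expand.grid(group = c("sevo_long", "sevo_short"),
                    target_volpct = sevo_top3)
fit_excl <- fit_consumption(targets, exclusions = excl)

pick <- function(fit, g1, g2) {
  ct <- fit$contrasts
  ct$p_value[(ct$group1 == g1 & ct$group2 == g2) |
             (ct$group1 == g2 & ct$group2 == g1)]
}
cat("ventilation-mode contrasts (long vs short inspiratory-flow time):\n")
cat(sprintf("  isoflurane:  p = %.4g\n", pick(fit_all, "iso_long", "iso_short")))
cat(sprintf("  sevoflurane: p = %.4g\n", pick(fit_all, "sevo_long", "sevo_short")))
cat("agent contrasts at matched concentration ranges (top 3 sevoflurane targets excluded):\n")
cat(sprintf("  short flow: p = %.4g\n", pick(fit_excl, "iso_short", "sevo_short")))
cat(sprintf("  long flow:  p = %.4g\n", pick(fit_excl, "iso_long", "sevo_long")))

coefs <- do.call(rbind, lapply(names(fit_all$coefficients), function(g)
  data.frame(group = g, term = names(fit_all$coefficients[[g]]),
             estimate = unname(fit_all$coefficients[[g]]))))
write_csv_atomic(round_numeric(coefs, 4), "results/05_fit_coefficients.csv")
write_csv_atomic(round_numeric(fit_all$contrasts, 4), "results/05_contrasts_all.csv")
write_csv_atomic(round_numeric(fit_excl$contrasts, 4),
                 "results/05_contrasts_matched_range.csv")

re_tab <- targets[!targets$low_target & !is.na(targets$re_percent),
                  c("experiment", "target_volpct", "mean_ec",
                    "vapour_per_breath_ml", "re_percent")]
re_tab <- re_tab[order(re_tab$experiment, re_tab$vapour_per_breath_ml), ]
write_csv_atomic(round_numeric(re_tab, 4), "results/05_re_vs_vapour.csv")
cat("wrote results/05_* tables\n")

# headline ordering: short flow should sit above long flow at the top
for (agent in c("iso", "sevo")) {
  tl <- targets[targets$group == paste0(agent, "_long"), ]
  ts <- targets[targets$group == paste0(agent, "_short"), ]
  top <- which.max(tl$target_volpct)
  cat(sprintf("%s top target: long %.2f vs short %.2f mL/h (short/long = %.2f)\n",
              agent, tl$hourly_rate_ml_h[top], ts$hourly_rate_ml_h[top],
              ts$hourly_rate_ml_h[top] / tl$hourly_rate_ml_h[top]))
}
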