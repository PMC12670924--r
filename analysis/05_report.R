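#!/usr/bin/env Rscript
# Stage 5: exposure-response summaries.
#
# Converts each posterior-mean exposure-level effect to the percent change
# in relative risk, (e^b - 1) * 100, with 95% intervals from the Laplace
# posterior, and flags levels whose interval excludes zero.

suppressPackageStartupMessages(library(climsent))

panel <- read_panel("results/panel_binned.csv")
attr(panel, "schemes") <- read_schemes("results/schemes.yaml")
theta <- compute_theta_tot(panel)
fused <- utils::read.csv("results/fused.csv", stringsAsFactors = FALSE)
fit <- fit_rr_model(panel, model_spec(), fused = fused, theta = theta)

summ <- summarize_rr(fit)
data.table::fwrite(summ, "results/rr_summary.csv")

for (i in seq_len(nrow(summ))) {
  message(sprintf("%-16s %-16s %+6.3f%% (95%% CI %+6.3f, %+6.3f)%s",
                  summ$covariate[i], summ$level_label[i],
                  summ$percent_change[i], summ$ci_low[i], summ$ci_high[i],
                  if (summ$significant[i]) "  *" else ""))
}
message("summary written to results/rr_summary.csv")
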