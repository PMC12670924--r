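#!/usr/bin/env Rscript
# Stage 2: categorise continuous exposures into ordered levels.
#
# Applies the shipped cut-point schemes (four temperature levels, four
# levels per pollen taxon, three mortality and drought levels, and a
# zero/at-least-one split for West Nile virus cases) and reports how the
# panel populates each level.

suppressPackageStartupMessages(library(climsent))

panel <- read_panel("results/panel.csv")
schemes <- default_schemes()
panel <- apply_schemes(panel, schemes)
write_panel(panel, "results/panel_binned.csv")
write_schemes(schemes, "results/schemes.yaml")

for (nm in names(schemes)) {
  tab <- tabulate(panel[[paste0(nm, "_level")]] + 1L,
                  length(schemes[[nm]]$labels))
  message(sprintf("%-16s %s", nm,
                  paste(sprintf("%s=%d", schemes[[nm]]$labels, tab),
                        collapse = " ")))
}
message("binned panel written to results/panel_binned.csv")
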