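#!/usr/bin/env Rscript
# Stage 4: displacement figures for the simulated experiment.
#
# One figure per tree: decile percentile-displacement curves versus time
# since the first scan, narrow-slab (invalid) percentiles in gray, the mean
# over valid percentiles in bold, classification in the subtitle.
#
# Outputs: results/figures/<tree>_displacement.svg

suppressPackageStartupMessages(library(canopymotion))

sim_root <- "scratch/sim"
if (!dir.exists(sim_root))
  stop("run analysis/01_simulate_scans.R first", call. = FALSE)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

for (dir in list.dirs(sim_root, recursive = FALSE)) {
  name <- basename(dir)
  series <- load_scan_series(file.path(dir, "manifest.csv"))
  reg <- register_series(series, read_targets(file.path(dir, "targets.csv")))
  ds <- displacement_series(reg$series,
                            read_canopy_frame(file.path(dir, "frame.json")))
  cls <- classify_movement(ds)
  f <- file.path("results/figures", sprintf("%s_displacement.svg", name))
  plot_displacement(ds, cls, f)
  cat(sprintf("%-12s -> %s (%s)\n", name, f, cls$primary_label))
}
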