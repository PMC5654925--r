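#!/usr/bin/env Rscript
# Stage 1: simulate the virtual overnight scanning experiment.
#
# Four potted crowns, one per movement type, scanned 18 times over 12.5 h
# (half-hourly in the evening and morning, hourly overnight) under the full
# scanner noise model: 0.95 mm ranging noise, +/- 1% ghost-point count
# fluctuation, and per-scan rigid offsets of at most 2.3 mm. Each tree's
# scans are written as xyz files with a manifest, sphere-target CSV, canopy
# frame JSON, and ground-truth JSON, so the later stages run from files
# exactly as they would on real exported scans.
#
# Outputs: scratch/sim/<tree>/ (bulky point clouds; regenerated on demand)

suppressPackageStartupMessages(library(canopymotion))

out_root <- "scratch/sim"
dir.create(out_root, showWarnings = FALSE, recursive = TRUE)
base_seed <- 20160916L

experiment <- list(
  nerium = list(  # circadian sleeper, 2 cm, lever-arm about the trunk base
    spec = tree_spec("nerium", "ellipsoid", height = 2.6, crown_diameter = 1.6,
                     crown_base_height = 0.7, point_count = 20000),
    model = motion_model(circadian_amplitude = 0.02, circadian_period = 11,
                         circadian_phase = 2, spatial_mode = "lever_arm")),
  gleditschia = list(  # unidirectional drift, 5 cm over the window
    spec = tree_spec("gleditschia", "cylinder", height = 3.4,
                     crown_diameter = 1.8, crown_base_height = 1.0,
                     point_count = 20000),
    model = motion_model(drift_rate = 0.05 / 12.5)),
  magnolia = list(  # short-period oscillation, 0.75 cm every 3 h
    spec = tree_spec("magnolia", "cone", height = 3.0, crown_diameter = 1.5,
                     crown_base_height = 0.6, point_count = 20000),
    model = motion_model(oscillation_amplitude = 0.0075,
                         oscillation_period = 3, oscillation_phase = 1)),
  olea = list(  # static control: any apparent movement is noise
    spec = tree_spec("olea", "ellipsoid", height = 2.2, crown_diameter = 1.3,
                     crown_base_height = 0.6, point_count = 20000),
    model = motion_model()))

for (i in seq_along(experiment)) {
  name <- names(experiment)[i]
  ex <- experiment[[name]]
  sim <- simulate_series(ex$spec, ex$model,
                         noise_model(seed = base_seed + i))
  dir <- file.path(out_root, name)
  dir.create(dir, showWarnings = FALSE)
  ids <- series_ids(sim$series)
  paths <- file.path(dir, paste0(ids, ".xyz"))
  for (k in seq_along(ids))
    write_point_cloud(sim$series$records[[k]]$cloud, paths[k])
  write.csv(data.frame(scan_id = ids,
                       timestamp = format(series_times(sim$series),
                                          "%Y-%m-%dT%H:%M:%S"),
                       path = paste0(ids, ".xyz")),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(sim$targets, file.path(dir, "targets.csv"), row.names = FALSE)
  write_canopy_frame(default_canopy_frame(ex$spec),
                     file.path(dir, "frame.json"))
  jsonlite::write_json(
    list(model = unclass(ex$model), times_h = sim$truth$times_h,
         field_m = sim$truth$field,
         max_offset_mm = 1000 * max(vapply(sim$truth$transforms, function(tr)
           sqrt(sum(tr$translation^2)), 0))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  cat(sprintf("%-12s %2d scans, %5d-%5d pts/scan, true |d|max %.2f cm\n",
              name, length(ids),
              min(vapply(sim$series$records, function(r) n_points(r$cloud), 0L)),
              max(vapply(sim$series$records, function(r) n_points(r$cloud), 0L)),
              100 * max(abs(sim$truth$field - sim$truth$field[1]))))
}
cat(sprintf("simulated experiment written under %s\n", out_root))
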