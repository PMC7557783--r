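#!/usr/bin/env Rscript
# Step 1 — stimulus geometry.
#
# Builds the three experimental conditions and documents how constant world
# speed in depth translates into accelerating retinal expansion: the key
# retinal speeds at the interval landmarks, and full frame-by-frame traces
# for the standard and extreme test intervals.

suppressPackageStartupMessages(library(loomdiscrim))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

geom <- looming_geometry()   # 2 cm line separation, 97 cm viewing, 85 Hz
conds <- lapply(c(speed_change = "speed_change", duration = "duration",
                  distance = "distance"), build_condition, geometry = geom)

# landmark retinal speeds (arcmin/s): interval onsets and the extremes of
# the maximum speed-change level
landmarks <- data.frame(
  quantity = c("speed-change standard, motion onset (40 cm/s at 117 cm)",
               "max level slow phase onset (10 cm/s at 117 cm)",
               "max level just after the step (70 cm/s)",
               "speed-discrimination standard onset (40 cm/s at 97 cm)"),
  arcmin_per_s = signif(c(
    expansion_rate(117, 40, geom),
    expansion_rate(117, 10, geom),
    {
      tr <- simulate_trace(conds$speed_change$test_levels[[7]], geom)
      tr$expansion_arcmin_per_s[tr$world_speed_cm_s == 70][1]
    },
    expansion_rate(97, 40, geom)), 3)
)
write.csv(landmarks, file.path(out_dir, "stimulus_landmarks.csv"),
          row.names = FALSE)
cat("Landmark retinal speeds (arcmin/s):\n")
print(landmarks, row.names = FALSE)

# full traces: the retinal speed roughly doubles over the standard interval
# even though the world speed never changes
tr_std <- simulate_trace(conds$speed_change$standard, geom)
write_trace_csv(tr_std, file.path(out_dir, "trace_speed_change_standard.csv"))
write_trace_csv(simulate_trace(conds$speed_change$test_levels[[7]], geom),
                file.path(out_dir, "trace_speed_change_max_level.csv"))
moving <- tr_std$expansion_arcmin_per_s[tr_std$world_speed_cm_s > 0]
cat(sprintf("\nStandard interval: %.1f -> %.1f arcmin/s over 1 s of motion\n",
            moving[1], moving[length(moving)]))

# design conservation: the duration condition equates distance, the
# distance condition equates duration, the catch interval breaks both
cat(sprintf("Duration-condition distances: %.2f-%.2f cm (target 28.7)\n",
            min(sapply(conds$duration$test_levels, schedule_distance)),
            max(sapply(conds$duration$test_levels, schedule_distance))))
cat(sprintf("Catch interval: %.1f cm in %.3f s at 40 cm/s\n",
            schedule_distance(conds$distance$catch),
            schedule_motion_duration(conds$distance$catch)))

for (nm in names(conds)) {
  condition_to_json(conds[[nm]], file.path(out_dir,
                                           paste0("condition_", nm, ".json")))
}
cat("\nWrote condition configs and traces to", out_dir, "\n")
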