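#!/usr/bin/env Rscript
# Stage 1: render a synthetic study cohort as raw sensor CSV streams.
#
# The generator plants per-participant-day ground truth (walking minutes,
# cadence, stride amplitude, home/satellite schedules) linked to PROMIS PF 6b
# T-scores through the default association coefficients, then renders
# duty-cycled accelerometer (10 s on / 20 s off @ 10 Hz) and GPS
# (1 min on / 10 min off) streams. Raw CSVs are bulky, so they go under
# scratch/ (not a deliverable); later stages summarise into results/.

suppressPackageStartupMessages(library(gaitmob))

seed <- 20230102
out <- "scratch/cohort"
cfg <- cohort_config(
  n_participants = 8, study_days = 28,
  survey_days = c(0, 7, 14, 21), window_days = 3
)

unlink(out, recursive = TRUE)
truth <- write_cohort(cfg, out, seed = seed)

message(sprintf("wrote %d participants x %d days to %s",
                cfg$n_participants, cfg$study_days, out))
message(sprintf("planted: %d valid days (%.1f%%), mean true steps %.0f/day, ",
                sum(truth$days$status == "valid"),
                100 * mean(truth$days$status == "valid"),
                mean(truth$days$steps_true[truth$days$status == "valid"])),
        sprintf("mean home time %.1f h, mean distance %.1f km",
                mean(truth$days$home_time_h[truth$days$status == "valid"]),
                mean(truth$days$distance_km[truth$days$status == "valid"])))
message("next: analysis/02_extract_daily_measures.R")
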