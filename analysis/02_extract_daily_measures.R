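#!/usr/bin/env Rscript
# Stage 2: raw sensor CSVs -> six daily digital measures per participant-day,
# plus coverage minutes and the valid-day flag; checks recovery against the
# generator's truth table.

suppressPackageStartupMessages({
  library(gaitmob)
  library(dplyr)
})

cohort_dir <- "scratch/cohort"
if (!file.exists(file.path(cohort_dir, "truth.csv"))) {
  stop("no cohort found; run analysis/01_simulate_cohort.R first")
}
dir.create("results", showWarnings = FALSE)

truth <- readr::read_csv(file.path(cohort_dir, "truth.csv"),
                         show_col_types = FALSE)
pids <- sort(unique(truth$participant_id))

daily <- bind_rows(lapply(pids, function(pid) {
  extract_participant_daily(file.path(cohort_dir, pid), pid)
}))
readr::write_csv(daily, "results/daily.csv")
message(sprintf("extracted %d participant-days (%d valid) -> results/daily.csv",
                nrow(daily), sum(daily$valid)))

# recovery vs planted truth on valid days
cmp <- daily |>
  filter(valid) |>
  inner_join(truth, by = c("participant_id", "date"),
             suffix = c("_est", "_true")) |>
  summarise(
    steps_mape = mean(abs(steps_adjusted - steps_true) / pmax(steps_true, 1)),
    cadence_mae = mean(abs(cadence_est - cadence_true), na.rm = TRUE),
    stride_mae = mean(abs(stride_accel_est - stride_accel_true), na.rm = TRUE),
    home_mae_h = mean(abs(home_time_h_est - home_time_h_true)),
    distance_mape = mean(abs(distance_km_est - distance_km_true) /
                           pmax(distance_km_true, 0.1)),
    locations_exact = mean(n_locations_est == n_locations_true)
  )
readr::write_csv(cmp, "results/recovery_vs_truth.csv")
message(sprintf(
  paste0("recovery on valid days: steps MAPE %.2f%%, cadence MAE %.2f ",
         "steps/min, stride MAE %.4f g, home MAE %.3f h, distance MAPE ",
         "%.2f%%, locations exact %.0f%%"),
  100 * cmp$steps_mape, cmp$cadence_mae, cmp$stride_mae, cmp$home_mae_h,
  100 * cmp$distance_mape, 100 * cmp$locations_exact))
message("next: analysis/03_align_and_adherence.R")
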