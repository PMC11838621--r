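#!/usr/bin/env Rscript
# Stage 3: data-quality accounting and survey alignment. Valid days
# (>= 960 min collected) are averaged inside a window around each completed
# survey; adherence is actual vs expected days, collected and valid.

suppressPackageStartupMessages({
  library(gaitmob)
  library(dplyr)
})

if (!file.exists("results/daily.csv")) {
  stop("run analysis/02_extract_daily_measures.R first")
}
daily <- readr::read_csv("results/daily.csv", show_col_types = FALSE)
surveys <- read_surveys("scratch/cohort/surveys.csv")
study_days <- 28
window_days <- 3   # surveys are 7 days apart in this cohort

adherence <- adherence_summary(daily, study_days)
readr::write_csv(adherence, "results/adherence.csv")
message(sprintf(
  "adherence: mean %.1f%% of expected days collected, %.1f%% valid",
  100 * mean(adherence$prop_collected), 100 * mean(adherence$prop_valid)))

aligned <- align_to_surveys(daily, surveys, window_days)
readr::write_csv(aligned, "results/aligned.csv")
message(sprintf("aligned %d survey observations (%d with >=1 valid window day)",
                nrow(aligned), sum(aligned$n_window_days > 0)))

enroll <- tibble::tibble(participant_id = unique(daily$participant_id),
                         enroll_date = min(daily$date))
fortnight <- first_fortnight_means(daily, enroll)
readr::write_csv(fortnight, "results/fortnight_means.csv")
message(sprintf("first-fortnight means for %d participants", nrow(fortnight)))
message("next: analysis/04_fit_models.R")
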