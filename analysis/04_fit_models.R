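#!/usr/bin/env Rscript
# Stage 4: longitudinal models on the aligned table.
#   - association: digital measure ~ PROM, participant random intercept +
#     random slope on months since baseline
#   - trend: digital measure ~ month (baseline level and monthly change)
#   - smartphone use: per-participant data quality and fortnight means ~
#     reported usage category (reference: >4 h/day)
# Coefficient tables are written in forest-plot-ready shape.

suppressPackageStartupMessages({
  library(gaitmob)
  library(dplyr)
})

for (f in c("results/aligned.csv", "results/adherence.csv",
            "results/fortnight_means.csv")) {
  if (!file.exists(f)) stop("run analysis/03_align_and_adherence.R first")
}
aligned <- readr::read_csv("results/aligned.csv", show_col_types = FALSE)
adherence <- readr::read_csv("results/adherence.csv", show_col_types = FALSE)
fortnight <- readr::read_csv("results/fortnight_means.csv",
                             show_col_types = FALSE)
surveys <- read_surveys("scratch/cohort/surveys.csv")
dir.create("results/fits", showWarnings = FALSE)

measures <- c("steps_adjusted", "cadence", "stride_accel", "home_time_h",
              "distance_km", "n_locations")

assoc <- list()
for (oc in measures) {
  for (pr in c("promis_t", "ecog", "eq_mobility")) {
    fit <- tryCatch(fit_prom_association(aligned, oc, pr),
                    error = function(e) NULL)
    if (!is.null(fit)) assoc[[paste(oc, pr, sep = "~")]] <- fit
  }
}
readr::write_csv(tidy_fit(assoc), "results/fits/association.csv")
steps_t <- assoc[["steps_adjusted~promis_t"]]$terms
row <- steps_t[steps_t$term == "promis_t", ]
message(sprintf(
  "steps ~ PROMIS T: +%.1f steps/day per T-point [%.1f, %.1f], p = %.2g",
  row$estimate, row$ci_low, row$ci_high, row$p))

trend <- lapply(measures, function(oc) {
  tryCatch(fit_trend(aligned, oc), error = function(e) NULL)
})
trend <- trend[!vapply(trend, is.null, logical(1))]
readr::write_csv(tidy_fit(trend), "results/fits/trend.csv")
ct <- tidy_fit(trend) |> filter(outcome == "cadence")
message(sprintf(
  "cadence trend: baseline %.1f steps/min, %+.3f steps/min per month",
  ct$estimate[ct$term == "(Intercept)"], ct$estimate[ct$term == "month"]))

usage_tbl <- surveys |>
  distinct(participant_id, usage_category)
usage_fits <- suppressWarnings(
  fit_usage_association(fortnight, adherence, usage_tbl))
readr::write_csv(tidy_fit(usage_fits), "results/fits/usage.csv")
ut <- tidy_fit(usage_fits) |> filter(term != "(Intercept)")
message(sprintf(
  "smartphone use: %d category contrasts, %d with p < 0.05 (planted null)",
  nrow(ut), sum(ut$p < 0.05, na.rm = TRUE)))
message("next: analysis/05_model_calibration.R")
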