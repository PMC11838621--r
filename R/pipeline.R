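#' Extract daily measures for one participant from raw CSV directories
#'
#' Reads every per-day accelerometer and GPS CSV under
#' `<dir>/accelerometer/` and `<dir>/gps/`, concatenates them into single
#' streams, and computes the six daily digital measures plus coverage
#' minutes.
#'
#' @param dir participant directory.
#' @param participant_id identifier attached to outputs.
#' @param tz IANA timezone.
#' @param gait a [gait_params()].
#' @param mobility a [mobility_params()].
#' @param accuracy_cutoff_m GPS accuracy filter.
#' @param duty accel/GPS duty metadata, as in [cohort_config()] defaults.
#' @return DailyMeasures tibble for the participant.
#' @export
extract_participant_daily <- function(dir, participant_id, tz = "UTC",
                                      gait = gait_params(),
                                      mobility = mobility_params(),
                                      accuracy_cutoff_m = 100,
                                      duty = list(accel_rate_hz = 10,
                                                  accel_on_s = 10,
                                                  accel_off_s = 20,
                                                  gps_on_s = 60,
                                                  gps_off_s = 600)) {
  read_all <- function(subdir, reader) {
    files <- sort(list.files(file.path(dir, subdir), full.names = TRUE,
                             pattern = "\\.csv$"))
    dplyr::bind_rows(lapply(files, reader))
  }
  acc_samples <- read_all("accelerometer", function(f) {
    read_accel_csv(f, tz, participant_id, duty$accel_rate_hz,
                   duty$accel_on_s, duty$accel_off_s)$samples
  })
  gps_fixes <- read_all("gps", function(f) {
    read_gps_csv(f, accuracy_cutoff_m, tz, participant_id,
                 duty$gps_on_s, duty$gps_off_s)$fixes
  })
  if (nrow(acc_samples) == 0 && nrow(gps_fixes) == 0) {
    return(assemble_daily(
      gait_daily(accel_stream(acc_samples, participant_id)),
      mobility_daily(gps_trace(tibble::tibble(t = numeric(), lat = numeric(),
                                              lon = numeric(),
                                              accuracy = numeric()),
                               participant_id, tz = tz)),
      tibble::tibble(participant_id = character(), date = as.Date(character()),
                     coverage_min = integer())))
  }
  stream <- accel_stream(acc_samples, participant_id, duty$accel_rate_hz,
                         duty$accel_on_s, duty$accel_off_s, tz)
  stream <- normalize_accel_units(stream)
  trace <- gps_trace(gps_fixes, participant_id, duty$gps_on_s,
                     duty$gps_off_s, tz)

  gait_df <- gait_daily(stream, gait)
  mob_df <- if (nrow(gps_fixes)) mobility_daily(trace, mobility) else
    tibble::tibble(participant_id = character(), date = as.Date(character()),
                   home_time_h = numeric(), distance_km = numeric(),
                   n_locations = integer())

  dates <- sort(unique(c(local_date(acc_samples$t, tz),
                         local_date(gps_fixes$t, tz))))
  cov <- tibble::tibble(
    participant_id = participant_id,
    date = dates,
    coverage_min = vapply(dates, function(d) {
      coverage_minutes(stream, trace, d, tz)
    }, integer(1))
  )
  assemble_daily(gait_df, mob_df, cov)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains simulate -> write raw CSVs -> extract daily measures -> valid-day
#' filtering -> adherence -> survey alignment -> mixed-effects models, and
#' writes `daily.csv`, `aligned.csv`, `adherence.csv`, `fits/*.csv`,
#' `report.md` and `manifest.json` under `out`.
#'
#' @param config a [cohort_config()].
#' @param out output directory (cohort raw data goes to `<out>/data`).
#' @param seed RNG seed; the run is reproducible from `(config, seed)`.
#' @param force overwrite existing output.
#' @return list with `daily`, `aligned`, `adherence`, `fits` (invisible).
#' @export
run_pipeline <- function(config = cohort_config(), out, seed = 1,
                         force = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out, "data")

  truth <- stage("simulate", write_cohort(config, data_dir, seed, force))
  message(sprintf("simulate: %d participants, %d participant-days written",
                  nrow(truth$participants), nrow(truth$days)))

  daily <- stage("extract", {
    dplyr::bind_rows(lapply(truth$participants$participant_id, function(pid) {
      extract_participant_daily(
        file.path(data_dir, pid), pid, config$tz,
        duty = list(accel_rate_hz = config$accel_rate_hz,
                    accel_on_s = config$accel_on_s,
                    accel_off_s = config$accel_off_s,
                    gps_on_s = config$gps_on_s,
                    gps_off_s = config$gps_off_s))
    }))
  })
  message(sprintf("extract: %d participant-days, %d valid",
                  nrow(daily), sum(daily$valid)))

  surveys <- stage("surveys",
                   read_surveys(file.path(data_dir, "surveys.csv")))
  adherence <- stage("adherence",
                     adherence_summary(daily, config$study_days))
  aligned <- stage("align",
                   align_to_surveys(daily, surveys, config$window_days))
  fortnight <- stage("align", {
    enroll <- tibble::tibble(
      participant_id = truth$participants$participant_id,
      enroll_date = config$start_date)
    first_fortnight_means(daily, enroll)
  })
  message(sprintf("align: %d survey observations, %d with window data",
                  nrow(aligned), sum(aligned$n_window_days > 0)))

  fits <- stage("model", {
    assoc <- list()
    for (oc in measure_cols) {
      for (pr in c("promis_t", "ecog")) {
        key <- paste(oc, pr, sep = "~")
        assoc[[key]] <- tryCatch(fit_prom_association(aligned, oc, pr),
                                 error = function(e) NULL)
      }
    }
    trend <- lapply(measure_cols, function(oc) {
      tryCatch(fit_trend(aligned, oc), error = function(e) NULL)
    })
    names(trend) <- measure_cols
    usage <- fit_usage_association(
      fortnight, adherence,
      truth$participants[, c("participant_id", "usage_category")])
    list(association = assoc[!vapply(assoc, is.null, logical(1))],
         trend = trend[!vapply(trend, is.null, logical(1))],
         usage = usage)
  })
  message(sprintf("model: %d association, %d trend, %d usage fits",
                  length(fits$association), length(fits$trend),
                  length(fits$usage)))

  stage("report", {
    readr::write_csv(daily, file.path(out, "daily.csv"), progress = FALSE)
    readr::write_csv(aligned, file.path(out, "aligned.csv"), progress = FALSE)
    readr::write_csv(adherence, file.path(out, "adherence.csv"),
                     progress = FALSE)
    fdir <- file.path(out, "fits")
    dir.create(fdir, showWarnings = FALSE)
    readr::write_csv(tidy_fit(fits$association),
                     file.path(fdir, "association.csv"), progress = FALSE)
    readr::write_csv(tidy_fit(fits$trend), file.path(fdir, "trend.csv"),
                     progress = FALSE)
    readr::write_csv(tidy_fit(fits$usage), file.path(fdir, "usage.csv"),
                     progress = FALSE)
    writeLines(pipeline_report(daily, adherence, aligned, fits),
               file.path(out, "report.md"))
    manifest <- list(
      seed = seed,
      package_version = as.character(utils::packageVersion("gaitmob")),
      rows = list(daily = nrow(daily), aligned = nrow(aligned),
                  adherence = nrow(adherence)))
    jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(list(daily = daily, aligned = aligned, adherence = adherence,
                 fortnight = fortnight, fits = fits, truth = truth))
}

pipeline_report <- function(daily, adherence, aligned, fits) {
  fmt_fits <- function(f) {
    td <- tidy_fit(f)
    c(sprintf("| %s | %s | %s | %.4g | [%.4g, %.4g] | %.3g |",
              td$outcome, td$predictor, td$term, td$estimate, td$ci_low,
              td$ci_high, td$p))
  }
  c("# Pipeline report",
    "",
    "## Data quality",
    sprintf("- participant-days: %d (%d valid, %.1f%%)", nrow(daily),
            sum(daily$valid), 100 * mean(daily$valid)),
    sprintf("- mean proportion of valid days per participant: %.3f",
            mean(adherence$prop_valid)),
    sprintf("- survey observations with window data: %d / %d",
            sum(aligned$n_window_days > 0), nrow(aligned)),
    "",
    "## Association models (outcome ~ PROM, random intercept + slope)",
    "",
    "| outcome | predictor | term | estimate | 95% CI | p |",
    "|---|---|---|---|---|---|",
    fmt_fits(fits$association),
    "",
    "## Trend models (outcome ~ month)",
    "",
    "| outcome | predictor | term | estimate | 95% CI | p |",
    "|---|---|---|---|---|---|",
    fmt_fits(fits$trend),
    "",
    "## Smartphone-use models",
    "",
    "| outcome | predictor | term | estimate | 95% CI | p |",
    "|---|---|---|---|---|---|",
    fmt_fits(fits$usage))
}
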