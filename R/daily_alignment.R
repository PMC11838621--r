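measure_cols <- c("steps_adjusted", "cadence", "stride_accel",
                  "home_time_h", "distance_km", "n_locations")

#' Minutes of collected data on a local date
#'
#' A minute counts as covered when at least one raw sample from either sensor
#' falls inside it — the most permissive deterministic reading of "collected
#' data", applied before the 960-minute valid-day rule.
#'
#' @param accel an [accel_stream()] (may be empty).
#' @param gps a [gps_trace()] (may be empty).
#' @param date local calendar date.
#' @param tz IANA timezone.
#' @return integer count in `[0, 1440]`.
#' @export
coverage_minutes <- function(accel, gps, date, tz = "UTC") {
  b <- day_bounds(date, tz)
  ts <- c(if (!is.null(accel)) accel$samples$t,
          if (!is.null(gps)) gps$fixes$t)
  ts <- ts[ts >= b[1] & ts < b[2]]
  if (!length(ts)) return(0L)
  length(unique(floor((ts - b[1]) / 60)))
}

#' Assemble the participant-day table from per-sensor daily summaries
#'
#' Full join of gait, mobility and coverage tables on participant and date.
#' Dates with accelerometer data but no detected walking get a step count of
#' zero (cadence and stride acceleration stay missing).
#'
#' @param gait daily gait tibble from [gait_daily()] (possibly several
#'   participants bound together).
#' @param mobility daily mobility tibble from [mobility_daily()].
#' @param coverage tibble `participant_id`, `date`, `coverage_min`.
#' @return DailyMeasures tibble with a `valid` flag (see
#'   [mark_valid_days()]).
#' @export
assemble_daily <- function(gait, mobility, coverage) {
  daily <- dplyr::full_join(gait, mobility,
                            by = c("participant_id", "date")) |>
    dplyr::full_join(coverage, by = c("participant_id", "date"))
  if (!"coverage_min" %in% names(daily)) daily$coverage_min <- NA_integer_
  daily$coverage_min[is.na(daily$coverage_min)] <- 0L
  has_accel <- !is.na(daily$walking_seconds_observed)
  daily$steps_adjusted[has_accel & is.na(daily$steps_adjusted)] <- 0L
  mark_valid_days(daily)
}

#' Flag valid days
#'
#' A valid day has at least 960 minutes (16 hours) of collected data;
#' the boundary is inclusive. All downstream analyses use valid days only.
#'
#' @param daily DailyMeasures tibble with a `coverage_min` column.
#' @param min_coverage_min validity threshold in minutes.
#' @return `daily` with a logical `valid` column.
#' @export
mark_valid_days <- function(daily, min_coverage_min = 960) {
  daily$valid <- daily$coverage_min >= min_coverage_min
  daily
}

#' Per-participant adherence and data-quality summary
#'
#' @param daily DailyMeasures tibble with `coverage_min` and `valid`.
#' @param days_expected expected days of collection: a single number, or a
#'   tibble `participant_id`, `days_expected` for per-participant spans.
#' @return tibble `participant_id`, `days_collected`, `days_valid`,
#'   `days_expected`, `prop_collected`, `prop_valid`.
#' @export
adherence_summary <- function(daily, days_expected) {
  if (is.numeric(days_expected)) {
    if (days_expected <= 0) stop("days_expected must be positive")
    exp_tbl <- tibble::tibble(
      participant_id = unique(daily$participant_id),
      days_expected = days_expected
    )
  } else {
    exp_tbl <- days_expected
    if (any(exp_tbl$days_expected <= 0)) stop("days_expected must be positive")
  }
  daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(days_collected = sum(.data$coverage_min > 0),
                     days_valid = sum(.data$valid),
                     .groups = "drop") |>
    dplyr::left_join(exp_tbl, by = "participant_id") |>
    dplyr::mutate(prop_collected = .data$days_collected / .data$days_expected,
                  prop_valid = .data$days_valid / .data$days_expected)
}

#' Align daily digital measures to completed surveys
#'
#' For each survey, each of the six digital measures is averaged over valid
#' days within `window_days` of the survey date (closed interval, so +/-10
#' days spans up to 21 days). Measures with no non-missing valid-day value in
#' the window are left missing.
#'
#' @param daily DailyMeasures tibble (with `date` and `valid`).
#' @param surveys survey tibble with `participant_id`, `survey_day` and
#'   `date` (completion date anchoring the window).
#' @param window_days half-width of the alignment window in days.
#' @return the survey rows augmented with the six window means and
#'   `n_window_days` (number of valid days contributing).
#' @export
align_to_surveys <- function(daily, surveys, window_days = 10) {
  valid <- daily[daily$valid, , drop = FALSE]
  out <- lapply(seq_len(nrow(surveys)), function(i) {
    sv <- surveys[i, ]
    win <- valid[valid$participant_id == sv$participant_id &
                   valid$date >= sv$date - window_days &
                   valid$date <= sv$date + window_days, , drop = FALSE]
    means <- lapply(measure_cols, function(mc) {
      v <- win[[mc]]
      if (is.null(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
    names(means) <- measure_cols
    dplyr::bind_cols(sv, tibble::as_tibble(means),
                     tibble::tibble(n_window_days = nrow(win)))
  })
  dplyr::bind_rows(out)
}

#' Per-participant means over the first two weeks of collection
#'
#' Averages each digital measure over valid days falling in study days 0-13,
#' the exposure window for the smartphone-use association analysis.
#'
#' @param daily DailyMeasures tibble.
#' @param enrollment optional tibble `participant_id`, `enroll_date`; when
#'   omitted each participant's first observed date is used as day 0.
#' @return tibble with one row per participant: the six fortnight means and
#'   `n_fortnight_days`.
#' @export
first_fortnight_means <- function(daily, enrollment = NULL) {
  if (is.null(enrollment)) {
    enrollment <- daily |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(enroll_date = min(.data$date), .groups = "drop")
  }
  daily |>
    dplyr::left_join(enrollment, by = "participant_id") |>
    dplyr::mutate(study_day = as.numeric(.data$date - .data$enroll_date)) |>
    dplyr::filter(.data$valid, .data$study_day >= 0, .data$study_day <= 13) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(measure_cols),
                    ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
      n_fortnight_days = dplyr::n(),
      .groups = "drop"
    )
}
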