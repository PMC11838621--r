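#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions the pipeline targets: 85
#' participants followed for 180 days with surveys at days 0/30/90/180,
#' accelerometer duty-cycled 10 s on / 20 s off at 10 Hz, GPS 1 min on /
#' 10 min off, and per-measure linear links to the PROMIS PF 6b T-score with
#' participant random intercepts and slopes. Measure intercepts and PROMIS
#' links sit at the published cohort scale (about 2,235 steps/day, cadence
#' 105.5 steps/min, stride acceleration 0.10 g, home time 14.9 h, distance
#' 79 km, 4 significant locations at the mean T-score of 44.4); ECOG
#' step-count offsets are available but default to zero so the steps scale
#' is governed by the PROMIS link alone.
#'
#' @param n_participants cohort size.
#' @param study_days follow-up length in days.
#' @param survey_days study days at which surveys are completed (must lie in
#'   `[0, study_days]`).
#' @param start_date local calendar date of study day 0.
#' @param tz IANA timezone of the cohort.
#' @param accel_rate_hz,accel_on_s,accel_off_s accelerometer sampling.
#' @param gps_on_s,gps_off_s,gps_fix_interval_s GPS sampling; one fix every
#'   `gps_fix_interval_s` seconds during on-windows.
#' @param accel_noise_g,gps_noise_m sensor noise SDs.
#' @param idle_accel `"keepalive"` (default) emits one idle sample per
#'   minute outside walking bouts — enough for coverage accounting while
#'   keeping file sizes realistic to work with; `"full"` emits the complete
#'   duty-cycled idle stream.
#' @param promis_t_mean,promis_t_sd per-wave PROMIS T-score distribution.
#' @param ecog_probs probabilities of ECOG PS 0-4 per wave.
#' @param eq_item_probs probabilities of EQ-5D-5L levels 1-5 (shared by the
#'   five items).
#' @param usage_probs probabilities of the five smartphone-use categories
#'   (most-use first).
#' @param measure_params per-measure generative parameters: `intercept` and
#'   `link_promis` on the PROM scale, `trend_month` fixed monthly change,
#'   random-effect SDs `sd_u0`/`sd_u1`, and day-level residual SD `sd_day`.
#' @param ecog_steps_offsets additive step-count offsets for ECOG levels 0-4
#'   (all zero by default; set to e.g. `c(0, -500, -1100, -1837, -1837)` to
#'   plant categorical effects).
#' @param valid_day_rate probability a study day is a valid day (>= 960 min
#'   coverage); `invalid_day_rate` is the probability of a collected but
#'   invalid day; the remainder is missing entirely.
#' @param invalid_day_rate see `valid_day_rate`.
#' @param trip_speed_kmh travel speed on flights.
#' @param window_days half-width (days) of the survey alignment window used
#'   by [run_pipeline()]; keep it below the survey spacing so aligned
#'   observations stay distinguishable (the default matches surveys 30+ days
#'   apart; miniature cohorts need a proportionally smaller window).
#' @param home_lat,home_lon latitude/longitude anchor of the first
#'   participant's home; homes are spread a few km apart.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_participants = 85, study_days = 180,
    survey_days = c(0, 30, 90, 180),
    start_date = as.Date("2023-01-02"), tz = "UTC",
    accel_rate_hz = 10, accel_on_s = 10, accel_off_s = 20,
    gps_on_s = 60, gps_off_s = 600, gps_fix_interval_s = 5,
    accel_noise_g = 0.02, gps_noise_m = 5,
    idle_accel = c("keepalive", "full"),
    promis_t_mean = 44.4, promis_t_sd = 8,
    ecog_probs = c(0.318, 0.541, 0.094, 0.035, 0.012),
    eq_item_probs = c(0.40, 0.35, 0.15, 0.07, 0.03),
    usage_probs = c(0.177, 0.329, 0.306, 0.106, 0.082),
    measure_params = default_measure_params(),
    ecog_steps_offsets = c(0, 0, 0, 0, 0),
    valid_day_rate = 0.741, invalid_day_rate = 0.13,
    trip_speed_kmh = 60, window_days = 10,
    home_lat = 42.33, home_lon = -71.10) {
  idle_accel <- match.arg(idle_accel)
  survey_days <- sort(unique(survey_days[survey_days <= study_days]))
  stopifnot(n_participants >= 1, study_days >= 1,
            valid_day_rate >= 0, valid_day_rate <= 1,
            valid_day_rate + invalid_day_rate <= 1,
            all(ecog_probs >= 0), all(measure_params$sd_u0 >= 0),
            all(measure_params$sd_u1 >= 0), all(measure_params$sd_day >= 0))
  cfg <- as.list(environment())
  cfg$ecog_probs <- ecog_probs / sum(ecog_probs)
  cfg$eq_item_probs <- eq_item_probs / sum(eq_item_probs)
  cfg$usage_probs <- usage_probs / sum(usage_probs)
  structure(cfg, class = "cohort_config")
}

#' Default per-measure generative parameters
#'
#' Intercepts and PROMIS links on the published association scale; monthly
#' trends at the published trend scale; random-effect and residual SDs chosen
#' so that a 4-wave, 85-participant cohort has realistic between- and
#' within-participant spread.
#'
#' @return tibble, one row per digital measure.
#' @export
default_measure_params <- function() {
  tibble::tibble(
    measure = c("steps_adjusted", "cadence", "stride_accel",
                "home_time_h", "distance_km", "n_locations"),
    intercept = c(-964.4, 99.2, 0.05, 12.5, 58.6, 2.7),
    link_promis = c(72.6, 0.13, 0.001, 0.06, 0.33, 0.03),
    trend_month = c(-38.62, -0.23, -0.001, 0.04, -2.93, -0.027),
    sd_u0 = c(800, 4, 0.015, 2, 12, 0.7),
    sd_u1 = c(20, 0.3, 0.001, 0.15, 2, 0.05),
    sd_day = c(500, 3, 0.01, 1.2, 8, 0.8)
  )
}

draw_level <- function(n, probs, values = seq_along(probs) - 1L) {
  values[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

# map a target T-score through the bundled raw<->T table so surveys carry a
# consistent (raw, t) pair
t_to_raw <- function(t_target, table) {
  idx <- vapply(t_target, function(ti) which.min(abs(table$t - ti)), integer(1))
  table$raw[idx]
}

#' Simulate cohort-level ground truth (no raw sensor data yet)
#'
#' Draws participants (random effects, usage category, home geometry),
#' per-wave survey responses, and the per-day truth table of the six digital
#' measures that [generate_participant_day()] then renders into raw streams.
#' Day-level measure means follow
#' `intercept + link * T_wave(day) + trend * month + u0 + u1 * month + noise`
#' with the wave taken as the nearest completed survey; values are lightly
#' clamped to physically realisable ranges before being turned into walking
#' and travel schedules, and the truth table records the *achieved* schedule
#' values so pipeline recovery can be checked exactly.
#'
#' @param config a [cohort_config()].
#' @param seed integer RNG seed; everything downstream is reproducible from
#'   `(config, seed)`.
#' @return list with `participants`, `surveys`, `days` tibbles.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  cf <- config
  mp <- cf$measure_params
  n <- cf$n_participants
  t_table <- promis_t_table_synthetic()

  pid <- sprintf("P%03d", seq_len(n))
  participants <- tibble::tibble(
    participant_id = pid,
    usage_category = factor(draw_level(n, cf$usage_probs, usage_levels),
                            levels = usage_levels),
    home_lat = cf$home_lat + (seq_len(n) - 1) * 0.05,
    home_lon = cf$home_lon
  )
  # participant random effects, one (u0, u1) pair per measure
  for (m in seq_len(nrow(mp))) {
    participants[[paste0("u0_", mp$measure[m])]] <- rnorm(n, 0, mp$sd_u0[m])
    participants[[paste0("u1_", mp$measure[m])]] <- rnorm(n, 0, mp$sd_u1[m])
  }

  waves <- cf$survey_days
  surveys <- tidyr::expand_grid(participant_id = pid, survey_day = waves)
  ns <- nrow(surveys)
  t_target <- rnorm(ns, cf$promis_t_mean, cf$promis_t_sd)
  surveys$promis_raw <- t_to_raw(t_target, t_table)
  surveys$promis_t <- promis_raw_to_t(surveys$promis_raw, t_table)
  surveys$ecog <- draw_level(ns, cf$ecog_probs)
  for (item in c("eq_mobility", "eq_selfcare", "eq_usual", "eq_pain",
                 "eq_anxiety")) {
    surveys[[item]] <- draw_level(ns, cf$eq_item_probs, 1:5)
  }
  surveys$date <- cf$start_date + surveys$survey_day
  surveys <- dplyr::left_join(
    surveys, participants[, c("participant_id", "usage_category")],
    by = "participant_id")

  days <- tidyr::expand_grid(participant_id = pid,
                             study_day = seq_len(cf$study_days) - 1L)
  nd <- nrow(days)
  days$date <- cf$start_date + days$study_day
  days$month <- days$study_day / DAYS_PER_MONTH
  # nearest completed survey governs the day's PROM level
  nearest_wave <- waves[max.col(-abs(outer(days$study_day, waves, "-")),
                                ties.method = "first")]
  days$wave <- nearest_wave
  days <- dplyr::left_join(
    days,
    surveys[, c("participant_id", "survey_day", "promis_t", "ecog")],
    by = c("participant_id", "wave" = "survey_day"))

  days <- dplyr::left_join(days, participants, by = "participant_id")
  for (m in seq_len(nrow(mp))) {
    me <- mp$measure[m]
    mu <- mp$intercept[m] + mp$link_promis[m] * days$promis_t +
      mp$trend_month[m] * days$month +
      days[[paste0("u0_", me)]] + days[[paste0("u1_", me)]] * days$month +
      rnorm(nd, 0, mp$sd_day[m])
    if (me == "steps_adjusted") mu <- mu + cf$ecog_steps_offsets[days$ecog + 1]
    days[[paste0("target_", me)]] <- mu
  }

  # day status: valid / collected-but-invalid / missing
  u <- runif(nd)
  days$status <- ifelse(u < cf$valid_day_rate, "valid",
                        ifelse(u < cf$valid_day_rate + cf$invalid_day_rate,
                               "invalid", "missing"))
  days$coverage_target_min <- ifelse(
    days$status == "valid", round(runif(nd, 1380, 1440)),
    ifelse(days$status == "invalid", round(runif(nd, 240, 959)), 0))

  # feasible gait plan: cadence inside the detector band, stride amplitude
  # above the spectral floor, walking minutes from the step target
  days$cadence <- pmin(pmax(days$target_cadence, 87), 135)
  days$stride_accel <- pmin(pmax(days$target_stride_accel, 0.07), 0.30)
  days$walking_min <- pmax(days$target_steps_adjusted, 0) / days$cadence
  days$walking_min <- pmin(days$walking_min, 120)
  days$steps_true <- round(days$walking_min * days$cadence)

  # feasible travel plan; truth records the *achieved* schedule values
  plan <- plan_mobility_day(
    home_h = days$target_home_time_h,
    dist_km = days$target_distance_km,
    n_loc = days$target_n_locations,
    speed_kmh = cf$trip_speed_kmh)
  days$distance_km <- plan$dist_km
  days$n_locations <- plan$n_loc
  days$depart_s <- plan$depart_s
  days$return_s <- plan$return_s
  days$bearing_deg <- runif(nd, 0, 360)
  days$day_seed <- sample.int(.Machine$integer.max - 1L, nd, replace = TRUE)

  # achieved home time comes from the fix-time-snapped schedule (the same
  # deterministic construction generate_participant_day renders), so pipeline
  # recovery can be checked against the truth exactly
  days$home_time_h <- 24
  away <- which(!is.na(days$depart_s))
  if (length(away)) {
    days$home_time_h[away] <- vapply(away, function(r) {
      s <- build_day_schedule(days[r, ], cf)
      (s$depart_s + 86400 - s$return_s) / 3600
    }, numeric(1))
  }

  keep <- c("participant_id", "study_day", "date", "month", "wave",
            "promis_t", "ecog", "status", "coverage_target_min",
            "walking_min", "cadence", "stride_accel", "steps_true",
            "home_time_h", "distance_km", "n_locations",
            "depart_s", "return_s", "bearing_deg", "day_seed")
  list(participants = participants, surveys = surveys,
       days = days[, keep])
}

# Turn target day-level mobility values into a feasible out-and-back travel
# plan: clamp targets, balance travel vs satellite pauses, and return the
# planned depart/return seconds-of-day (NA when the day is spent at home).
plan_mobility_day <- function(home_h, dist_km, n_loc, speed_kmh) {
  n <- length(home_h)
  n_loc <- pmin(pmax(round(n_loc), 1L), 6L)
  k <- n_loc - 1L
  home_h <- pmin(pmax(home_h, 2), 24)
  dist_km <- pmin(pmax(dist_km, 0), 400)

  away <- pmin(pmax(24 - home_h, 0), 11.5)
  stay_home <- k == 0L | away < 1 | dist_km < 1
  away[stay_home] <- 0
  # travel must fit with >= 15-min pauses at each satellite (we use >= 0.4 h
  # so detected pauses clear the 900 s filter with margin)
  max_travel <- pmax(away - k * 0.4, 0)
  travel <- pmin(dist_km / speed_kmh, max_travel)
  dist_km <- travel * speed_kmh
  stay_home <- stay_home | travel <= 0
  away[stay_home] <- 0
  dist_km[stay_home] <- 0
  k[stay_home] <- 0L
  n_loc <- k + 1L

  depart <- (14 - away / 2) * 3600
  ret <- depart + away * 3600
  depart[stay_home] <- NA_real_
  ret[stay_home] <- NA_real_
  home_h <- ifelse(stay_home, 24, 24 - away)
  list(home_h = home_h, dist_km = dist_km, n_loc = n_loc,
       depart_s = depart, return_s = ret)
}

# fix-time grid (seconds of day) for a duty-cycled GPS sensor
gps_fix_grid <- function(on_s, off_s, interval_s, day_len = 86400) {
  cyc <- seq(0, day_len - 1, by = on_s + off_s)
  offs <- seq(0, on_s - interval_s, by = interval_s)
  sort(as.vector(outer(offs, cyc, "+")))
}

# nearest grid element (the grid is irregular: 5-s steps inside on-windows,
# ~10-min jumps across off-periods, so a floor-style snap would be biased)
snap_to_grid <- function(t, grid) {
  lo <- pmin(pmax(findInterval(t, grid), 1L), length(grid))
  hi <- pmin(lo + 1L, length(grid))
  ifelse(abs(grid[hi] - t) < abs(t - grid[lo]), grid[hi], grid[lo])
}

#' Render one participant-day of raw sensor data from its truth row
#'
#' Accelerometer: walking is laid down as whole 30-s duty cycles inside a
#' 09:00-19:00 activity window; within on-bouts the vector magnitude is
#' `1 + A * sin(2 * pi * (cadence / 60) * t)` decomposed onto the axes with a
#' random (per-day) device orientation plus Gaussian sensor noise. GPS: fixes
#' follow the day's planted home/satellite schedule with fix noise. Both
#' streams are truncated to the day's planted coverage minutes.
#'
#' @param day one row of `simulate_cohort()$days`.
#' @param participant the matching row of `$participants`.
#' @param config the [cohort_config()].
#' @return list with `accel` (tibble `t`, `x`, `y`, `z`) and `gps` (tibble
#'   `t`, `lat`, `lon`, `accuracy`); both empty on missing days.
#' @export
generate_participant_day <- function(day, participant, config) {
  cf <- config
  empty <- list(accel = tibble::tibble(t = numeric(), x = numeric(),
                                       y = numeric(), z = numeric()),
                gps = tibble::tibble(t = numeric(), lat = numeric(),
                                     lon = numeric(), accuracy = numeric()))
  if (day$status == "missing" || day$coverage_target_min <= 0) return(empty)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(day$day_seed)

  day_start <- day_bounds(day$date, cf$tz)[1]
  cutoff <- day$coverage_target_min * 60
  cycle <- cf$accel_on_s + cf$accel_off_s
  rate <- cf$accel_rate_hz

  ## --- accelerometer ---
  n_cycles <- round(day$walking_min * 60 / cycle)
  act_lo <- 9 * 3600 %/% cycle
  act_hi <- min(19 * 3600, cutoff) %/% cycle - 1
  avail <- seq(act_lo, max(act_lo, act_hi))
  n_cycles <- min(n_cycles, length(avail))
  walk_cycles <- if (n_cycles > 0) {
    sort(avail[sample.int(length(avail), n_cycles)])
  } else integer()

  within_bout <- seq(0, cf$accel_on_s - 1 / rate, by = 1 / rate)
  f_step <- day$cadence / 60
  A <- day$stride_accel * pi / 2

  t_walk <- as.vector(outer(within_bout, walk_cycles * cycle, "+"))
  vm_walk <- 1 + A * sin(2 * pi * f_step * t_walk)

  if (cf$idle_accel == "full") {
    all_cycles <- seq(0, cutoff %/% cycle - 1)
    idle_cycles <- setdiff(all_cycles, walk_cycles)
    t_idle <- as.vector(outer(within_bout, idle_cycles * cycle, "+"))
  } else {
    t_idle <- seq(15, cutoff - 1, by = 60)
  }
  vm_idle <- rep(1, length(t_idle))

  t_acc <- c(t_walk, t_idle)
  vm <- c(vm_walk, vm_idle)
  ord <- order(t_acc)
  t_acc <- t_acc[ord]; vm <- vm[ord]
  dup <- duplicated(round(t_acc * 1000))
  t_acc <- t_acc[!dup]; vm <- vm[!dup]
  keepers <- t_acc < cutoff
  t_acc <- t_acc[keepers]; vm <- vm[keepers]

  u <- rnorm(3); u <- u / sqrt(sum(u^2))  # random device orientation
  na <- length(t_acc)
  accel <- tibble::tibble(
    t = day_start + t_acc,
    x = vm * u[1] + rnorm(na, 0, cf$accel_noise_g),
    y = vm * u[2] + rnorm(na, 0, cf$accel_noise_g),
    z = vm * u[3] + rnorm(na, 0, cf$accel_noise_g)
  )

  ## --- GPS ---
  grid <- gps_fix_grid(cf$gps_on_s, cf$gps_off_s, cf$gps_fix_interval_s)
  tf <- grid[grid < cutoff]
  pos <- schedule_positions(tf, day, cf)
  nrow_f <- length(tf)
  R <- 6371000
  x_noisy <- pos$x + rnorm(nrow_f, 0, cf$gps_noise_m)
  y_noisy <- pos$y + rnorm(nrow_f, 0, cf$gps_noise_m)
  gps <- tibble::tibble(
    t = day_start + tf,
    lat = participant$home_lat + (y_noisy / R) * 180 / pi,
    lon = participant$home_lon +
      (x_noisy / (R * cos(participant$home_lat * pi / 180))) * 180 / pi,
    accuracy = 10
  )
  list(accel = accel, gps = gps)
}

# Build the day's movement schedule as straight segments between waypoints
# (home -> satellites along a ray -> home), with all pause boundaries snapped
# to GPS fix times so detected pauses start and end on an observed fix.
# `day` needs depart_s, return_s, distance_km, n_locations, bearing_deg.
build_day_schedule <- function(day, cf) {
  k <- day$n_locations - 1L
  grid <- gps_fix_grid(cf$gps_on_s, cf$gps_off_s, cf$gps_fix_interval_s)
  th <- day$bearing_deg * pi / 180
  rmax <- day$distance_km * 1000 / 2
  px <- c(0, (seq_len(k) / k) * rmax * cos(th), 0)
  py <- c(0, (seq_len(k) / k) * rmax * sin(th), 0)
  leg_len <- sqrt(diff(px)^2 + diff(py)^2)
  speed <- cf$trip_speed_kmh / 3.6
  travel_s <- sum(leg_len) / speed
  pause_each <- (day$return_s - day$depart_s - travel_s) / k

  t_cur <- snap_to_grid(day$depart_s, grid)
  depart_s <- t_cur
  seg <- list()
  for (m in seq_len(k + 1)) {
    arr <- snap_to_grid(t_cur + leg_len[m] / speed, grid)
    seg[[length(seg) + 1]] <- c(t_cur, arr, px[m], py[m], px[m + 1], py[m + 1])
    if (m <= k) {
      leave <- snap_to_grid(arr + pause_each, grid)
      seg[[length(seg) + 1]] <- c(arr, leave, px[m + 1], py[m + 1],
                                  px[m + 1], py[m + 1])
      t_cur <- leave
    } else {
      t_cur <- arr
    }
  }
  m <- do.call(rbind, seg)
  list(segments = m, depart_s = depart_s, return_s = t_cur)
}

# planar (x, y) meters relative to home for each second-of-day in `tf`
schedule_positions <- function(tf, day, cf) {
  x <- numeric(length(tf)); y <- numeric(length(tf))
  k <- day$n_locations - 1L
  if (is.na(day$depart_s) || k < 1) return(list(x = x, y = y))
  m <- build_day_schedule(day, cf)$segments
  for (s in seq_len(nrow(m))) {
    sel <- tf >= m[s, 1] & tf < m[s, 2]
    if (!any(sel)) next
    frac <- (tf[sel] - m[s, 1]) / max(m[s, 2] - m[s, 1], 1e-9)
    x[sel] <- m[s, 3] + frac * (m[s, 5] - m[s, 3])
    y[sel] <- m[s, 4] + frac * (m[s, 6] - m[s, 4])
  }
  list(x = x, y = y)
}

#' Write a full synthetic cohort to disk
#'
#' Layout: `<out>/<participant_id>/accelerometer/<date>.csv`,
#' `<out>/<participant_id>/gps/<date>.csv`, plus `surveys.csv`, `truth.csv`
#' (the day-level truth table) and `manifest.json` (config + seed). Refuses
#' to write into an existing non-empty directory unless `force = TRUE`.
#'
#' @param config a [cohort_config()].
#' @param out output directory.
#' @param seed RNG seed.
#' @param force overwrite an existing non-empty directory.
#' @return the truth list from [simulate_cohort()], invisibly.
#' @export
write_cohort <- function(config = cohort_config(), out, seed = 1,
                         force = FALSE) {
  if (dir.exists(out) && length(list.files(out)) > 0 && !force) {
    stop("output directory exists and is not empty: ", out,
         " (use force = TRUE)")
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_cohort(config, seed)

  for (i in seq_len(nrow(truth$participants))) {
    p <- truth$participants[i, ]
    pdir <- file.path(out, p$participant_id)
    dir.create(file.path(pdir, "accelerometer"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(pdir, "gps"), recursive = TRUE, showWarnings = FALSE)
    pdays <- truth$days[truth$days$participant_id == p$participant_id, ]
    for (d in seq_len(nrow(pdays))) {
      day <- pdays[d, ]
      if (day$status == "missing") next
      raw <- generate_participant_day(day, p, config)
      if (nrow(raw$accel)) {
        write_accel_csv(
          accel_stream(raw$accel, p$participant_id, config$accel_rate_hz,
                       config$accel_on_s, config$accel_off_s, config$tz),
          file.path(pdir, "accelerometer", paste0(day$date, ".csv")))
      }
      if (nrow(raw$gps)) {
        write_gps_csv(
          gps_trace(raw$gps, p$participant_id, config$gps_on_s,
                    config$gps_off_s, config$tz),
          file.path(pdir, "gps", paste0(day$date, ".csv")))
      }
    }
  }
  readr::write_csv(truth$surveys, file.path(out, "surveys.csv"),
                   progress = FALSE)
  readr::write_csv(truth$days, file.path(out, "truth.csv"), progress = FALSE)
  manifest <- c(
    lapply(unclass(config)[!vapply(unclass(config), is.data.frame, logical(1))],
           function(v) if (inherits(v, "Date")) format(v) else v),
    list(measure_params = config$measure_params, seed = seed,
         package_version = as.character(utils::packageVersion("gaitmob"))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

#' Simulate an aligned observation table directly (no raw sensors)
#'
#' Fast generator of survey-aligned observations for mixed-model studies:
#' `outcome = intercept + effect(predictor) + u0 + u1 * month + residual`.
#' Used for parameter-recovery and CI-calibration simulations where the raw
#' sensor rendering is irrelevant.
#'
#' @param n_participants cohort size.
#' @param survey_days survey schedule (study days).
#' @param predictor `"promis"` (continuous T-score, slope `link`), `"ecog"`
#'   (categorical offsets `ecog_offsets`), or `"none"`.
#' @param link slope per PROMIS T-point.
#' @param ecog_offsets additive offsets for ECOG levels 0-4.
#' @param intercept outcome intercept.
#' @param sd_u0,sd_u1,sd_resid random-intercept, random-slope (per month) and
#'   residual SDs.
#' @param trend_month fixed monthly change added to every observation.
#' @param promis_t_mean,promis_t_sd PROMIS T distribution.
#' @param ecog_probs ECOG level probabilities.
#' @param outcome name of the outcome column.
#' @return tibble with `participant_id`, `survey_day`, `month`, the
#'   predictor column(s) and the outcome.
#' @export
simulate_aligned_cohort <- function(
    n_participants = 85, survey_days = c(0, 30, 90, 180),
    predictor = c("promis", "ecog", "none"),
    link = 72.6, ecog_offsets = c(0, -500, -1100, -1837, -1837),
    intercept = -964.4, sd_u0 = 800, sd_u1 = 20, sd_resid = 400,
    trend_month = 0, promis_t_mean = 44.4, promis_t_sd = 8,
    ecog_probs = c(0.318, 0.541, 0.094, 0.035, 0.012),
    outcome = "steps_adjusted") {
  predictor <- match.arg(predictor)
  n <- n_participants
  obs <- tidyr::expand_grid(participant_id = sprintf("P%03d", seq_len(n)),
                            survey_day = survey_days)
  obs$month <- obs$survey_day / DAYS_PER_MONTH
  u0 <- rnorm(n, 0, sd_u0)
  u1 <- rnorm(n, 0, sd_u1)
  idx <- match(obs$participant_id, sprintf("P%03d", seq_len(n)))
  mu <- intercept + u0[idx] + u1[idx] * obs$month + trend_month * obs$month
  if (predictor == "promis") {
    obs$promis_t <- rnorm(nrow(obs), promis_t_mean, promis_t_sd)
    mu <- mu + link * obs$promis_t
  } else if (predictor == "ecog") {
    obs$ecog <- draw_level(nrow(obs), ecog_probs / sum(ecog_probs))
    mu <- mu + ecog_offsets[obs$ecog + 1]
  }
  obs[[outcome]] <- mu + rnorm(nrow(obs), 0, sd_resid)
  obs
}
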