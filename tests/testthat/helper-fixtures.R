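# Fixture builders shared across test files. All synthetic, built in code.

# Duty-cycled accelerometer stream whose vector magnitude is
# 1 + A * sin(2 * pi * f * t), projected on a fixed axis.
make_walking_stream <- function(f, A = 0.3, total_s = 1800, rate = 10,
                                duty_on = 10, duty_off = 20, noise = 0,
                                axis = c(0, 0, 1), t0 = 0, tz = "UTC") {
  t <- seq(0, total_s - 1 / rate, by = 1 / rate)
  cyc <- floor(t / (duty_on + duty_off))
  on <- (t - cyc * (duty_on + duty_off)) < duty_on
  tt <- t[on]
  vm <- 1 + A * sin(2 * pi * f * tt)
  if (noise > 0) vm <- vm + rnorm(length(vm), 0, noise)
  axis <- axis / sqrt(sum(axis^2))
  accel_stream(
    tibble::tibble(t = t0 + tt, x = vm * axis[1], y = vm * axis[2],
                   z = vm * axis[3]),
    participant_id = "T01", nominal_rate_hz = rate,
    duty_on_s = duty_on, duty_off_s = duty_off, tz = tz
  )
}

# Brute-force step oracle: per on-bout, count upward crossings of the bout
# mean of the vector magnitude (one crossing per gait cycle = one step).
zero_crossing_steps <- function(stream) {
  vm_df <- vector_magnitude(stream)
  ids <- cumsum(c(TRUE, diff(vm_df$t) > 1))
  sum(vapply(split(vm_df$vm, ids), function(v) {
    d <- v - mean(v)
    sum(d[-length(d)] < 0 & d[-1] >= 0)
  }, numeric(1)))
}

# GPS trace from planar meter coordinates near a reference point
planar_to_trace <- function(t, x, y, lat0 = 42, lon0 = -71, accuracy = 10,
                            tz = "UTC", id = "T01") {
  R <- 6371000
  gps_trace(
    tibble::tibble(
      t = t,
      lat = lat0 + (y / R) * 180 / pi,
      lon = lon0 + (x / (R * cos(lat0 * pi / 180))) * 180 / pi,
      accuracy = accuracy
    ),
    participant_id = id, tz = tz
  )
}

# daily-measure table builder for alignment tests
make_daily <- function(pid, dates, coverage = 1440, steps = 2000,
                       cadence = 105, stride = 0.1, home = 15, dist = 10,
                       nloc = 3) {
  n <- length(dates)
  mark_valid_days(tibble::tibble(
    participant_id = pid, date = as.Date(dates),
    steps_adjusted = rep_len(steps, n), cadence = rep_len(cadence, n),
    stride_accel = rep_len(stride, n), home_time_h = rep_len(home, n),
    distance_km = rep_len(dist, n), n_locations = rep_len(nloc, n),
    walking_seconds_observed = 600,
    coverage_min = rep_len(coverage, n)
  ))
}

tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
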