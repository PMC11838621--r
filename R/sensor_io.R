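#' Construct a raw accelerometer stream
#'
#' A stream holds time-ordered tri-axial samples plus the duty-cycle metadata
#' needed to adjust step counts for the on/off sampling scheme (phones record
#' 10 s of data followed by a 20 s pause to spare the battery).
#'
#' @param samples tibble/data.frame with columns `t` (seconds since epoch,
#'   UTC), `x`, `y`, `z` (acceleration in g after normalisation).
#' @param participant_id opaque participant identifier.
#' @param nominal_rate_hz nominal sampling rate during on-bouts (Hz).
#' @param duty_on_s,duty_off_s duty-cycle on/off durations in seconds.
#' @param tz IANA timezone used to derive local calendar days.
#' @return an object of class `accel_stream`.
#' @export
accel_stream <- function(samples, participant_id = NA_character_,
                         nominal_rate_hz = 10, duty_on_s = 10,
                         duty_off_s = 20, tz = "UTC") {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("t", "x", "y", "z") %in% names(samples)))
  if (nrow(samples) > 1 && any(diff(samples$t) <= 0)) {
    stop("accelerometer timestamps must be strictly increasing")
  }
  structure(
    list(participant_id = participant_id, samples = samples,
         nominal_rate_hz = nominal_rate_hz, duty_on_s = duty_on_s,
         duty_off_s = duty_off_s, tz = tz),
    class = "accel_stream"
  )
}

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf("<accel_stream> participant %s: %d samples @ %g Hz, duty %g/%g s\n",
              x$participant_id, nrow(x$samples), x$nominal_rate_hz,
              x$duty_on_s, x$duty_off_s))
  invisible(x)
}

#' Construct a GPS trace
#'
#' @param fixes tibble/data.frame with columns `t` (seconds since epoch),
#'   `lat`, `lon` (degrees), `accuracy` (meters).
#' @param participant_id opaque participant identifier.
#' @param duty_on_s,duty_off_s GPS duty cycle (default 1 min on / 10 min off).
#' @param tz IANA timezone used to derive local calendar days.
#' @return an object of class `gps_trace`.
#' @export
gps_trace <- function(fixes, participant_id = NA_character_,
                      duty_on_s = 60, duty_off_s = 600, tz = "UTC") {
  fixes <- tibble::as_tibble(fixes)
  stopifnot(all(c("t", "lat", "lon", "accuracy") %in% names(fixes)))
  if (nrow(fixes)) {
    if (any(diff(fixes$t) <= 0)) stop("GPS timestamps must be strictly increasing")
    if (any(fixes$lat < -90 | fixes$lat > 90)) stop("latitude out of [-90, 90]")
    if (any(fixes$lon < -180 | fixes$lon > 180)) stop("longitude out of [-180, 180]")
    if (any(fixes$accuracy <= 0)) stop("accuracy must be positive")
  }
  structure(
    list(participant_id = participant_id, fixes = fixes,
         duty_on_s = duty_on_s, duty_off_s = duty_off_s, tz = tz),
    class = "gps_trace"
  )
}

#' @export
print.gps_trace <- function(x, ...) {
  cat(sprintf("<gps_trace> participant %s: %d fixes, duty %g/%g s\n",
              x$participant_id, nrow(x$fixes), x$duty_on_s, x$duty_off_s))
  invisible(x)
}

accel_cols <- c("timestamp", "UTC time", "accuracy", "x", "y", "z")
gps_cols <- c("timestamp", "UTC time", "latitude", "longitude", "altitude",
              "accuracy")

#' Read a raw accelerometer CSV file
#'
#' Expects the six-column raw-dialect header
#' `timestamp,UTC time,accuracy,x,y,z` with `timestamp` in integer
#' milliseconds since epoch. Rows are sorted by time and duplicate timestamps
#' dropped (first kept). An empty file yields an empty stream.
#'
#' @param path CSV file path.
#' @param tz IANA timezone for local-day derivation.
#' @param participant_id participant identifier attached to the stream.
#' @inheritParams accel_stream
#' @return an [accel_stream()].
#' @export
read_accel_csv <- function(path, tz = "UTC", participant_id = NA_character_,
                           nominal_rate_hz = 10, duty_on_s = 10,
                           duty_off_s = 20) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    return(accel_stream(tibble::tibble(t = numeric(), x = numeric(),
                                       y = numeric(), z = numeric()),
                        participant_id, nominal_rate_hz, duty_on_s,
                        duty_off_s, tz))
  }
  missing <- setdiff(accel_cols, names(df))
  if (length(missing)) {
    stop("accelerometer CSV is missing columns: ",
         paste(missing, collapse = ", "))
  }
  df <- df[order(df$timestamp), ]
  df <- df[!duplicated(df$timestamp), ]
  accel_stream(
    tibble::tibble(t = as.numeric(df$timestamp) / 1000,
                   x = as.numeric(df$x), y = as.numeric(df$y),
                   z = as.numeric(df$z)),
    participant_id, nominal_rate_hz, duty_on_s, duty_off_s, tz
  )
}

#' Write an accelerometer stream back to the raw CSV dialect
#'
#' Inverse of [read_accel_csv()]; axis values are written with six decimal
#' places so a read/write round trip preserves them to that precision.
#'
#' @param stream an [accel_stream()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(stream, path) {
  s <- stream$samples
  df <- data.frame(
    timestamp = format(round(s$t * 1000), scientific = FALSE, trim = TRUE),
    `UTC time` = format(as.POSIXct(s$t, origin = "1970-01-01", tz = "UTC"),
                        "%Y-%m-%dT%H:%M:%OS3"),
    accuracy = "unknown",
    x = sprintf("%.6f", s$x), y = sprintf("%.6f", s$y),
    z = sprintf("%.6f", s$z),
    check.names = FALSE
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Normalize accelerometer units to g
#'
#' Device dialects report either g or m/s^2. If the median vector magnitude
#' exceeds 4 the stream is assumed to be in m/s^2 and all axes are divided by
#' the standard gravity 9.80665; otherwise the stream is returned unchanged.
#' Idempotent; never changes sample count or order.
#'
#' @param stream an [accel_stream()].
#' @return the stream in g units.
#' @export
normalize_accel_units <- function(stream) {
  s <- stream$samples
  if (nrow(s) == 0) return(stream)
  vm_med <- median(sqrt(s$x^2 + s$y^2 + s$z^2))
  if (is.finite(vm_med) && vm_med > 4) {
    stream$samples$x <- s$x / 9.80665
    stream$samples$y <- s$y / 9.80665
    stream$samples$z <- s$z / 9.80665
  }
  stream
}

#' Read a raw GPS CSV file
#'
#' Expects header `timestamp,UTC time,latitude,longitude,altitude,accuracy`
#' (`timestamp` in ms). Fixes are sorted, deduplicated (first kept), and
#' fixes with reported accuracy worse than `accuracy_cutoff_m` are dropped:
#' poor fixes masquerade as movement and corrupt pause detection.
#'
#' @param path CSV file path.
#' @param accuracy_cutoff_m maximum accepted accuracy radius in meters.
#' @param tz IANA timezone for local-day derivation.
#' @param participant_id participant identifier.
#' @inheritParams gps_trace
#' @return a [gps_trace()].
#' @export
read_gps_csv <- function(path, accuracy_cutoff_m = 100, tz = "UTC",
                         participant_id = NA_character_,
                         duty_on_s = 60, duty_off_s = 600) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    return(gps_trace(tibble::tibble(t = numeric(), lat = numeric(),
                                    lon = numeric(), accuracy = numeric()),
                     participant_id, duty_on_s, duty_off_s, tz))
  }
  missing <- setdiff(gps_cols, names(df))
  if (length(missing)) {
    stop("GPS CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  df <- df[order(df$timestamp), ]
  df <- df[!duplicated(df$timestamp), ]
  df <- df[df$accuracy <= accuracy_cutoff_m, ]
  gps_trace(
    tibble::tibble(t = as.numeric(df$timestamp) / 1000,
                   lat = as.numeric(df$latitude),
                   lon = as.numeric(df$longitude),
                   accuracy = as.numeric(df$accuracy)),
    participant_id, duty_on_s, duty_off_s, tz
  )
}

#' Write a GPS trace back to the raw CSV dialect
#'
#' @param trace a [gps_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gps_csv <- function(trace, path) {
  f <- trace$fixes
  df <- data.frame(
    timestamp = format(round(f$t * 1000), scientific = FALSE, trim = TRUE),
    `UTC time` = format(as.POSIXct(f$t, origin = "1970-01-01", tz = "UTC"),
                        "%Y-%m-%dT%H:%M:%OS3"),
    latitude = sprintf("%.8f", f$lat),
    longitude = sprintf("%.8f", f$lon),
    altitude = 0,
    accuracy = f$accuracy,
    check.names = FALSE
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
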