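#' Local calendar date of epoch timestamps
#'
#' Sensor timestamps are seconds since the Unix epoch (UTC). Daily summaries
#' use local midnight-to-midnight days in the participant's timezone.
#'
#' @param t numeric vector, seconds since epoch.
#' @param tz IANA timezone name (e.g. `"UTC"`, `"America/New_York"`).
#' @return a `Date` vector.
#' @export
local_date <- function(t, tz = "UTC") {
  as.Date(as.POSIXct(t, origin = "1970-01-01", tz = tz), tz = tz)
}

#' Epoch-second bounds of a local calendar day
#'
#' @param date a `Date` (or string coercible to one).
#' @param tz IANA timezone name.
#' @return numeric length-2 vector `c(start, end)`; `end` is the start of the
#'   next day, so the interval is `[start, end)`. Days spanning a DST
#'   transition are shorter or longer than 86400 s.
#' @export
day_bounds <- function(date, tz = "UTC") {
  date <- as.Date(date)
  start <- as.numeric(as.POSIXct(format(date), tz = tz))
  end <- as.numeric(as.POSIXct(format(date + 1L), tz = tz))
  c(start, end)
}

#' Seconds-of-day of epoch timestamps in local time
#' @noRd
local_seconds_of_day <- function(t, tz = "UTC") {
  lt <- as.POSIXlt(as.POSIXct(t, origin = "1970-01-01", tz = tz), tz = tz)
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

# overlap (seconds) of intervals [a0, a1] with a single interval [b0, b1]
interval_overlap <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0))
}
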