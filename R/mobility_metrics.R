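#' Parameters for GPS trajectory segmentation and mobility measures
#'
#' Pause *detection* (50 m radius, 5 min minimum) is deliberately finer than
#' the *significant-location* filter (pauses of at least 15 minutes, clusters
#' at least 50 m apart), so that short stops still anchor the trajectory while
#' only substantial visits count as locations.
#'
#' @param pause_radius_m radius (m) within which fixes form a pause; also the
#'   displacement threshold deciding whether a sampling gap is bridged as a
#'   pause or a straight flight.
#' @param min_pause_s minimum duration (s) of a detected pause.
#' @param max_heading_change_deg heading change (degrees) that starts a new
#'   flight, operationalising travel "without a directional change".
#' @param min_sig_pause_s minimum pause duration (s) to count as a
#'   significant-location candidate (15 min).
#' @param merge_radius_m cluster separation (m) for significant locations.
#' @param night_start_h,night_end_h local hours bounding the night window
#'   (20:00 to 08:00) used to define the home location.
#' @return a list of class `mobility_params`.
#' @export
mobility_params <- function(pause_radius_m = 50, min_pause_s = 300,
                            max_heading_change_deg = 30,
                            min_sig_pause_s = 900, merge_radius_m = 50,
                            night_start_h = 20, night_end_h = 8) {
  structure(list(pause_radius_m = pause_radius_m, min_pause_s = min_pause_s,
                 max_heading_change_deg = max_heading_change_deg,
                 min_sig_pause_s = min_sig_pause_s,
                 merge_radius_m = merge_radius_m,
                 night_start_h = night_start_h, night_end_h = night_end_h),
            class = "mobility_params")
}

#' Project GPS fixes onto a local plane
#'
#' Equirectangular projection about the trace's median latitude/longitude:
#' `x = R * dlon * cos(lat_med)`, `y = R * dlat` (radians, R = 6,371,000 m).
#' At daily travel scales the distortion relative to geodesic distances is
#' far below the GPS noise floor.
#'
#' @param trace a [gps_trace()].
#' @return tibble with columns `t`, `x`, `y` (meters); the projection origin
#'   `(lat, lon)` is attached as attribute `origin`.
#' @export
project_to_plane <- function(trace) {
  f <- trace$fixes
  stopifnot(nrow(f) > 0)
  R <- 6371000
  lat0 <- median(f$lat); lon0 <- median(f$lon)
  out <- tibble::tibble(
    t = f$t,
    x = R * (f$lon - lon0) * pi / 180 * cos(lat0 * pi / 180),
    y = R * (f$lat - lat0) * pi / 180
  )
  attr(out, "origin") <- c(lat = lat0, lon = lon0)
  out
}

#' Construct trajectory elements
#'
#' A trajectory is a tibble of time-contiguous elements: Pauses (stationary,
#' `x0 == x1`) and straight Flights. This constructor is mostly useful for
#' building trajectories directly in tests and examples.
#'
#' @param type `"pause"` or `"flight"` (vectorised).
#' @param start_t,end_t epoch seconds.
#' @param x0,y0,x1,y1 planar endpoints in meters.
#' @return tibble with one row per element.
#' @export
traj_row <- function(type, start_t, end_t, x0, y0, x1, y1) {
  tibble::tibble(type = type, start_t = start_t, end_t = end_t,
                 x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' Segment planar fixes into flights and pauses
#'
#' Greedy scan: a maximal run of fixes that all stay within `pause_radius_m`
#' of the run's running centroid and spans at least `min_pause_s` becomes a
#' Pause. Between pauses consecutive fixes form straight Flights, with a new
#' Flight started whenever the heading turns by more than
#' `max_heading_change_deg`. The result covers observed time only; duty-cycle
#' gaps remain and are closed by [impute_gaps()].
#'
#' @param fixes planar fixes from [project_to_plane()].
#' @param params a [mobility_params()].
#' @return trajectory tibble with columns `type` ("pause"/"flight"),
#'   `start_t`, `end_t`, `x0`, `y0`, `x1`, `y1` (pauses have `x0 == x1`).
#' @export
segment_flights_pauses <- function(fixes, params = mobility_params()) {
  n <- nrow(fixes)
  if (n == 0) return(traj_row(character(), numeric(), numeric(),
                              numeric(), numeric(), numeric(), numeric()))
  t <- fixes$t; x <- fixes$x; y <- fixes$y
  if (n == 1) {
    return(traj_row("pause", t, t + 1, x, y, x, y))
  }

  pause_of <- rep(0L, n)
  pid <- 0L
  i <- 1L
  while (i <= n) {
    j <- i; cx <- x[i]; cy <- y[i]; k <- 1L
    while (j < n &&
           sqrt((x[j + 1] - cx)^2 + (y[j + 1] - cy)^2) < params$pause_radius_m) {
      j <- j + 1L; k <- k + 1L
      cx <- cx + (x[j] - cx) / k
      cy <- cy + (y[j] - cy) / k
    }
    if (t[j] - t[i] >= params$min_pause_s) {
      pid <- pid + 1L
      pause_of[i:j] <- pid
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }

  rows <- list()
  if (pid > 0) {
    for (p in seq_len(pid)) {
      idx <- which(pause_of == p)
      rows[[length(rows) + 1]] <- traj_row(
        "pause", t[idx[1]], t[idx[length(idx)]],
        mean(x[idx]), mean(y[idx]), mean(x[idx]), mean(y[idx])
      )
    }
  }

  # flights over maximal stretches of non-pause fixes
  free <- which(pause_of == 0L)
  if (length(free) > 1) {
    stretch <- split(free, cumsum(c(TRUE, diff(free) != 1L)))
    for (st in stretch) {
      if (length(st) < 2) next
      dx <- diff(x[st]); dy <- diff(y[st])
      head_deg <- atan2(dy, dx) * 180 / pi
      moving <- sqrt(dx^2 + dy^2) > 0
      # carry last defined heading through zero-displacement segments
      for (q in seq_along(head_deg)) {
        if (!moving[q] && q > 1) head_deg[q] <- head_deg[q - 1]
      }
      turn <- abs(((diff(head_deg) + 180) %% 360) - 180)
      brk <- c(TRUE, turn > params$max_heading_change_deg)
      fl_id <- cumsum(brk)
      for (fl in unique(fl_id)) {
        seg <- which(fl_id == fl)
        a <- st[seg[1]]; b <- st[seg[length(seg)] + 1L]
        if (t[b] <= t[a]) next
        len <- sqrt((x[b] - x[a])^2 + (y[b] - y[a])^2)
        if (len <= 0) {
          rows[[length(rows) + 1]] <- traj_row("pause", t[a], t[b],
                                               x[a], y[a], x[a], y[a])
        } else {
          rows[[length(rows) + 1]] <- traj_row("flight", t[a], t[b],
                                               x[a], y[a], x[b], y[b])
        }
      }
    }
  }

  traj <- dplyr::bind_rows(rows)
  traj[order(traj$start_t), ]
}

#' Bridge sampling gaps so the trajectory is continuous in time
#'
#' For every gap between consecutive trajectory elements the displacement
#' between the flanking observed positions decides the fill: below
#' `pause_radius_m` the gap becomes a Pause at the midpoint (the device did
#' not move appreciably), otherwise a single constant-speed straight Flight.
#' Leading/trailing gaps out to `span` are filled as Pauses at the nearest
#' observed position. This simple displacement rule preserves the per-day
#' time-conservation contract (pauses + flights cover every second).
#'
#' @param traj trajectory from [segment_flights_pauses()].
#' @param params a [mobility_params()].
#' @param span optional numeric `c(start, end)` epoch seconds to which the
#'   trajectory is extended (typically local-midnight bounds).
#' @return gap-free trajectory tibble.
#' @export
impute_gaps <- function(traj, params = mobility_params(), span = NULL) {
  if (nrow(traj) == 0) {
    if (is.null(span)) return(traj)
    stop("cannot impute an empty trajectory over a span: no anchor position")
  }
  traj <- traj[order(traj$start_t), ]
  rows <- list()
  for (e in seq_len(nrow(traj) - 1)) {
    gap <- traj$start_t[e + 1] - traj$end_t[e]
    if (gap <= 0) next
    p0 <- c(traj$x1[e], traj$y1[e])
    p1 <- c(traj$x0[e + 1], traj$y0[e + 1])
    d <- sqrt(sum((p1 - p0)^2))
    if (d < params$pause_radius_m) {
      m <- (p0 + p1) / 2
      rows[[length(rows) + 1]] <- traj_row("pause", traj$end_t[e],
                                           traj$start_t[e + 1],
                                           m[1], m[2], m[1], m[2])
    } else {
      rows[[length(rows) + 1]] <- traj_row("flight", traj$end_t[e],
                                           traj$start_t[e + 1],
                                           p0[1], p0[2], p1[1], p1[2])
    }
  }
  if (!is.null(span)) {
    if (span[1] < traj$start_t[1]) {
      rows[[length(rows) + 1]] <- traj_row("pause", span[1], traj$start_t[1],
                                           traj$x0[1], traj$y0[1],
                                           traj$x0[1], traj$y0[1])
    }
    nlast <- nrow(traj)
    if (span[2] > traj$end_t[nlast]) {
      rows[[length(rows) + 1]] <- traj_row("pause", traj$end_t[nlast], span[2],
                                           traj$x1[nlast], traj$y1[nlast],
                                           traj$x1[nlast], traj$y1[nlast])
    }
  }
  out <- dplyr::bind_rows(c(list(traj), rows))
  out[order(out$start_t), ]
}

#' Cluster qualifying pauses into significant locations
#'
#' Pauses lasting at least `min_sig_pause_s` (15 min) are candidates.
#' Candidates are clustered greedily in descending-duration order: a
#' candidate joins the first existing cluster whose centroid lies within
#' `merge_radius_m` (centroid updated as the duration-weighted mean),
#' otherwise it founds a new cluster.
#'
#' @param traj gap-free trajectory from [impute_gaps()].
#' @param params a [mobility_params()].
#' @return list with `clusters` (tibble `location_id`, `x`, `y`,
#'   `total_pause_s`) and `pauses` (candidate pauses with their assigned
#'   `location_id`).
#' @export
significant_locations <- function(traj, params = mobility_params()) {
  p <- traj[traj$type == "pause", , drop = FALSE]
  p$duration <- p$end_t - p$start_t
  p <- p[p$duration >= params$min_sig_pause_s, , drop = FALSE]
  empty <- list(
    clusters = tibble::tibble(location_id = integer(), x = numeric(),
                              y = numeric(), total_pause_s = numeric()),
    pauses = tibble::tibble(start_t = numeric(), end_t = numeric(),
                            x = numeric(), y = numeric(),
                            duration = numeric(), location_id = integer())
  )
  if (nrow(p) == 0) return(empty)
  ord <- order(p$duration, decreasing = TRUE)
  cx <- numeric(); cy <- numeric(); cw <- numeric()
  assign <- integer(nrow(p))
  for (i in ord) {
    placed <- FALSE
    for (cl in seq_along(cx)) {
      if (sqrt((p$x0[i] - cx[cl])^2 + (p$y0[i] - cy[cl])^2) <
          params$merge_radius_m) {
        w <- cw[cl] + p$duration[i]
        cx[cl] <- (cx[cl] * cw[cl] + p$x0[i] * p$duration[i]) / w
        cy[cl] <- (cy[cl] * cw[cl] + p$y0[i] * p$duration[i]) / w
        cw[cl] <- w
        assign[i] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cx <- c(cx, p$x0[i]); cy <- c(cy, p$y0[i]); cw <- c(cw, p$duration[i])
      assign[i] <- length(cx)
    }
  }
  list(
    clusters = tibble::tibble(location_id = seq_along(cx), x = cx, y = cy,
                              total_pause_s = cw),
    pauses = tibble::tibble(start_t = p$start_t, end_t = p$end_t,
                            x = p$x0, y = p$y0, duration = p$duration,
                            location_id = assign)
  )
}

#' Number of significant locations visited on a date
#'
#' @param sig output of [significant_locations()].
#' @param date local calendar date.
#' @param tz IANA timezone.
#' @return count of clusters with at least one qualifying pause overlapping
#'   the date.
#' @export
n_locations_on_date <- function(sig, date, tz = "UTC") {
  if (nrow(sig$pauses) == 0) return(0L)
  b <- day_bounds(date, tz)
  ov <- interval_overlap(sig$pauses$start_t, sig$pauses$end_t, b[1], b[2])
  length(unique(sig$pauses$location_id[ov > 0]))
}

# total seconds of [start, end] falling inside nightly local windows
# (night_start_h .. 24 and 0 .. night_end_h)
night_overlap <- function(start_t, end_t, tz, night_start_h, night_end_h) {
  total <- 0
  d0 <- local_date(start_t, tz) - 1
  d1 <- local_date(end_t, tz) + 1
  for (d in seq(as.numeric(d0), as.numeric(d1))) {
    b <- day_bounds(as.Date(d, origin = "1970-01-01"), tz)
    total <- total +
      interval_overlap(start_t, end_t, b[1], b[1] + night_end_h * 3600) +
      interval_overlap(start_t, end_t, b[1] + night_start_h * 3600, b[2])
  }
  total
}

#' Home location of a participant
#'
#' Among significant-location clusters, home is the one with the greatest
#' total pause time inside the nightly 20:00-08:00 local windows, pooled
#' over the whole collection period.
#'
#' @param sig output of [significant_locations()] on the participant's full
#'   (all-days) trajectory.
#' @param tz IANA timezone.
#' @param params a [mobility_params()].
#' @return numeric `c(x, y)` of the home centroid, or `NULL` when no
#'   night-time pause exists.
#' @export
home_location <- function(sig, tz = "UTC", params = mobility_params()) {
  if (nrow(sig$pauses) == 0) return(NULL)
  nt <- vapply(seq_len(nrow(sig$pauses)), function(i) {
    night_overlap(sig$pauses$start_t[i], sig$pauses$end_t[i], tz,
                  params$night_start_h, params$night_end_h)
  }, numeric(1))
  per_cluster <- tapply(nt, sig$pauses$location_id, sum)
  if (all(per_cluster == 0)) return(NULL)
  best <- as.integer(names(per_cluster)[which.max(per_cluster)])
  cl <- sig$clusters[sig$clusters$location_id == best, ]
  c(x = cl$x, y = cl$y)
}

#' Daily time at home
#'
#' Total duration within the local date of pause elements whose centroid lies
#' within `merge_radius_m` of the home location, in hours. Accumulates over
#' the whole day, not only the night window that defines home.
#'
#' @param traj gap-free trajectory.
#' @param date local calendar date.
#' @param home `c(x, y)` from [home_location()].
#' @param tz IANA timezone.
#' @param params a [mobility_params()].
#' @return hours at home, or `NA` when `home` is undefined.
#' @export
daily_home_time <- function(traj, date, home, tz = "UTC",
                            params = mobility_params()) {
  if (is.null(home)) return(NA_real_)
  p <- traj[traj$type == "pause", , drop = FALSE]
  if (nrow(p) == 0) return(0)
  b <- day_bounds(date, tz)
  at_home <- sqrt((p$x0 - home[[1]])^2 + (p$y0 - home[[2]])^2) <
    params$merge_radius_m
  sum(interval_overlap(p$start_t[at_home], p$end_t[at_home], b[1], b[2])) / 3600
}

#' Daily distance traveled
#'
#' Sum of straight-flight lengths intersecting the local date, in km; flights
#' straddling midnight are apportioned by the time fraction inside the day.
#'
#' @param traj gap-free trajectory.
#' @param date local calendar date.
#' @param tz IANA timezone.
#' @return kilometers traveled.
#' @export
daily_distance <- function(traj, date, tz = "UTC") {
  f <- traj[traj$type == "flight", , drop = FALSE]
  if (nrow(f) == 0) return(0)
  b <- day_bounds(date, tz)
  dur <- f$end_t - f$start_t
  frac <- interval_overlap(f$start_t, f$end_t, b[1], b[2]) / pmax(dur, 1e-9)
  len <- sqrt((f$x1 - f$x0)^2 + (f$y1 - f$y0)^2)
  sum(len * frac) / 1000
}

#' Daily mobility measures from a raw GPS trace
#'
#' Projects, segments, imputes to full local-day coverage, clusters
#' significant locations, derives the home location from night-time pauses,
#' and summarises home time, distance traveled, and number of significant
#' locations per date.
#'
#' @param trace a [gps_trace()].
#' @param params a [mobility_params()].
#' @return tibble with one row per date: `participant_id`, `date`,
#'   `home_time_h`, `distance_km`, `n_locations`.
#' @export
mobility_daily <- function(trace, params = mobility_params()) {
  empty <- tibble::tibble(participant_id = character(),
                          date = as.Date(character()),
                          home_time_h = numeric(), distance_km = numeric(),
                          n_locations = integer())
  if (nrow(trace$fixes) == 0) return(empty)
  tz <- trace$tz
  fixes <- project_to_plane(trace)
  traj <- segment_flights_pauses(fixes, params)
  dates <- seq(local_date(min(fixes$t), tz), local_date(max(fixes$t), tz),
               by = "day")
  span <- c(day_bounds(dates[1], tz)[1],
            day_bounds(dates[length(dates)], tz)[2])
  traj <- impute_gaps(traj, params, span = span)
  sig <- significant_locations(traj, params)
  home <- home_location(sig, tz, params)
  purrr::map_dfr(dates, function(d) {
    tibble::tibble(
      participant_id = trace$participant_id,
      date = d,
      home_time_h = daily_home_time(traj, d, home, tz, params),
      distance_km = daily_distance(traj, d, tz),
      n_locations = n_locations_on_date(sig, d, tz)
    )
  })
}
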