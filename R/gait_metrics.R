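#' Parameters for the spectral walking classifier
#'
#' Walking is detected second-by-second from the dominant frequency of the
#' acceleration vector magnitude within each duty-cycle on-bout. The band
#' defaults cover typical adult step frequencies; the amplitude floor rejects
#' low-energy oscillations (phone resting on a vibrating surface etc.).
#'
#' @param walk_f_min,walk_f_max admissible step-frequency band (steps/s).
#' @param min_peak_amp minimum spectral amplitude of the dominant tone (g).
#' @return a list of class `gait_params`.
#' @export
gait_params <- function(walk_f_min = 1.4, walk_f_max = 2.3,
                        min_peak_amp = 0.1) {
  stopifnot(walk_f_min > 0, walk_f_max > walk_f_min, min_peak_amp >= 0)
  structure(list(walk_f_min = walk_f_min, walk_f_max = walk_f_max,
                 min_peak_amp = min_peak_amp), class = "gait_params")
}

#' Orientation-invariant acceleration magnitude
#'
#' `vm = sqrt(x^2 + y^2 + z^2)`, in g; approximately 1 g when the phone is at
#' rest regardless of its orientation.
#'
#' @param stream an [accel_stream()] in g units.
#' @return tibble with columns `t` and `vm`.
#' @export
vector_magnitude <- function(stream) {
  s <- stream$samples
  tibble::tibble(t = s$t, vm = sqrt(s$x^2 + s$y^2 + s$z^2))
}

# split sample index into duty-cycle on-bouts: a new bout starts whenever the
# inter-sample gap exceeds 1 s (off periods are 20 s)
bout_ids <- function(t, max_gap_s = 1) {
  if (!length(t)) return(integer())
  cumsum(c(TRUE, diff(t) > max_gap_s))
}

#' Classify each observed second as walking or not
#'
#' Per duty-cycle on-bout the vector magnitude is resampled to a uniform grid
#' at the nominal rate, demeaned, and Fourier-transformed (zero-padded so the
#' frequency resolution is well below 0.1 Hz). Every whole second covered by
#' the bout is labelled walking iff the dominant spectral frequency lies in
#' `[walk_f_min, walk_f_max]` and its amplitude reaches `min_peak_amp`;
#' walking seconds carry that frequency as their one-second step frequency.
#' Bouts shorter than 2 s cannot support the spectral estimate and are marked
#' non-walking.
#'
#' @param stream an [accel_stream()] in g units.
#' @param params a [gait_params()].
#' @return tibble with one row per observed second: `second_start` (epoch s),
#'   `is_walking`, `step_freq` (steps/s; 0 when not walking),
#'   `peak_amplitude` (g).
#' @export
classify_walking <- function(stream, params = gait_params()) {
  vm_df <- vector_magnitude(stream)
  rate <- stream$nominal_rate_hz
  empty <- tibble::tibble(second_start = numeric(), is_walking = logical(),
                          step_freq = numeric(), peak_amplitude = numeric())
  if (nrow(vm_df) == 0) return(empty)

  ids <- bout_ids(vm_df$t)
  starts <- which(c(TRUE, diff(ids) != 0))
  ends <- c(starts[-1] - 1L, length(ids))

  # resample every bout to its own uniform grid
  n_bouts <- length(starts)
  res <- vector("list", n_bouts)
  span <- numeric(n_bouts)
  t0 <- numeric(n_bouts)
  for (b in seq_len(n_bouts)) {
    idx <- starts[b]:ends[b]
    tb <- vm_df$t[idx]
    t0[b] <- tb[1]
    span[b] <- tb[length(tb)] - tb[1]
    if (span[b] < 2 || length(idx) < 4) next
    n_u <- max(4L, round(span[b] * rate) + 1L)
    grid <- seq(tb[1], tb[length(tb)], length.out = n_u)
    v <- approx(tb, vm_df$vm[idx], xout = grid)$y
    res[[b]] <- v - mean(v)
  }

  dom_f <- rep(NA_real_, n_bouts)
  dom_a <- rep(0, n_bouts)
  lens <- vapply(res, length, integer(1))
  for (L in unique(lens[lens > 0])) {
    sel <- which(lens == L)
    nfft <- 2^ceiling(log2(max(L, rate / 0.1))) * 4L  # fine grid for peak
    mat <- matrix(0, nrow = nfft, ncol = length(sel))
    for (j in seq_along(sel)) mat[seq_len(L), j] <- res[[sel[j]]]
    spec <- Mod(stats::mvfft(mat))[2:(nfft %/% 2), , drop = FALSE] * 2 / L
    kmax <- max.col(t(spec), ties.method = "first")
    dom_f[sel] <- kmax * rate / nfft
    dom_a[sel] <- spec[cbind(kmax, seq_along(sel))]
  }

  walk <- !is.na(dom_f) & dom_f >= params$walk_f_min &
    dom_f <= params$walk_f_max & dom_a >= params$min_peak_amp

  sec0 <- floor(t0)
  n_sec <- floor(t0 + span) - sec0 + 1L
  idx <- rep.int(seq_len(n_bouts), n_sec)
  tibble::tibble(
    second_start = sequence(n_sec) - 1 + sec0[idx],
    is_walking = walk[idx],
    step_freq = ifelse(walk[idx], dom_f[idx], 0),
    peak_amplitude = dom_a[idx]
  )
}

#' Daily step count adjusted for the duty cycle
#'
#' Observed steps are the sum of one-second step frequencies over walking
#' seconds; because the sensor records only `duty_on / (duty_on + duty_off)`
#' of the time, the observed sum is scaled by `(on + off) / on` (3 for the
#' default 10 s / 20 s scheme) and rounded to an integer count.
#'
#' @param seconds output of [classify_walking()] restricted to one
#'   participant-day.
#' @param duty_on_s,duty_off_s duty-cycle durations (seconds).
#' @return integer adjusted step count.
#' @export
daily_step_count <- function(seconds, duty_on_s = 10, duty_off_s = 20) {
  observed <- sum(seconds$step_freq[seconds$is_walking])
  as.integer(round(observed * (duty_on_s + duty_off_s) / duty_on_s))
}

#' Daily gait cadence
#'
#' Mean one-second step frequency over all walking seconds, expressed in
#' steps per minute. Missing (`NA`) when the day has no walking seconds.
#'
#' @param seconds output of [classify_walking()] for one participant-day.
#' @return cadence in steps/minute, or `NA`.
#' @export
daily_cadence <- function(seconds) {
  f <- seconds$step_freq[seconds$is_walking]
  if (!length(f)) return(NA_real_)
  60 * mean(f)
}

#' Daily stride acceleration
#'
#' Within contiguous runs of walking seconds, step peaks are located as local
#' maxima of the smoothed vector magnitude (centered moving average of width
#' `rate / 4` samples, minimum peak spacing `1 / walk_f_max` s). A stride is
#' the segment between peak i and peak i+2 (two consecutive steps); each
#' stride is linearly rescaled to a 100-sample template and scored as the
#' mean absolute deviation of vm from the 1 g gravity baseline. The daily
#' value is the mean stride score. For a sinusoidal vm of amplitude A the
#' score is 2A/pi.
#'
#' @param stream the [accel_stream()] (g units) the seconds were derived from.
#' @param seconds output of [classify_walking()] for one participant-day.
#' @param params a [gait_params()].
#' @param template_len number of samples strides are rescaled to.
#' @return mean stride acceleration in g, or `NA` when no complete stride.
#' @export
stride_acceleration <- function(stream, seconds, params = gait_params(),
                                template_len = 100) {
  walk_secs <- seconds$second_start[seconds$is_walking]
  if (!length(walk_secs)) return(NA_real_)
  vm_df <- vector_magnitude(stream)
  rate <- stream$nominal_rate_hz
  runs <- split(walk_secs, cumsum(c(TRUE, diff(walk_secs) > 1)))

  min_space <- max(2L, floor(rate / params$walk_f_max))
  w <- max(3L, round(rate / 4))
  if (w %% 2 == 0) w <- w + 1L

  scores <- numeric(0)
  for (run in runs) {
    lo <- run[1]; hi <- run[length(run)] + 1
    idx <- which(vm_df$t >= lo & vm_df$t < hi)
    if (length(idx) < 2 * min_space + 1) next
    v <- vm_df$vm[idx]
    sm <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
    sm[is.na(sm)] <- v[is.na(sm)]
    pk <- find_peaks(sm, min_space)
    if (length(pk) < 3) next
    for (i in seq_len(length(pk) - 2)) {
      seg <- v[pk[i]:pk[i + 2]]
      if (length(seg) < 3) next
      # spline (not linear) resampling: chords under-integrate |vm - 1|
      # near step peaks at 10 Hz sampling
      tmpl <- stats::spline(seq_along(seg), seg, n = template_len)$y
      scores <- c(scores, mean(abs(tmpl - 1)))
    }
  }
  if (!length(scores)) return(NA_real_)
  mean(scores)
}

# local maxima with greedy highest-first suppression at min_space samples
find_peaks <- function(x, min_space) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer())
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer()
  for (p in cand) {
    if (all(abs(p - keep) >= min_space)) keep <- c(keep, p)
  }
  sort(keep)
}

#' Daily gait measures from a raw accelerometer stream
#'
#' Runs the walking classifier once and summarises per local calendar day:
#' duty-cycle-adjusted step count, cadence, stride acceleration, and the
#' number of observed walking seconds.
#'
#' @param stream an [accel_stream()] in g units.
#' @param params a [gait_params()].
#' @return tibble with one row per date: `participant_id`, `date`,
#'   `steps_adjusted`, `cadence`, `stride_accel`, `walking_seconds_observed`.
#' @export
gait_daily <- function(stream, params = gait_params()) {
  seconds <- classify_walking(stream, params)
  if (nrow(seconds) == 0) {
    return(tibble::tibble(participant_id = character(), date = as.Date(character()),
                          steps_adjusted = integer(), cadence = numeric(),
                          stride_accel = numeric(),
                          walking_seconds_observed = integer()))
  }
  seconds$date <- local_date(seconds$second_start, stream$tz)
  seconds |>
    dplyr::group_by(date = .data$date) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(
        steps_adjusted = daily_step_count(df, stream$duty_on_s, stream$duty_off_s),
        cadence = daily_cadence(df),
        stride_accel = stride_acceleration(stream, df, params),
        walking_seconds_observed = sum(df$is_walking)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(participant_id = stream$participant_id, .before = 1)
}
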