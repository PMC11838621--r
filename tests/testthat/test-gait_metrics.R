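test_that("vector magnitude is orientation invariant", {
  s <- accel_stream(tibble::tibble(
    t = 1:3, x = c(0, 1, 0.6), y = c(0, 0, 0), z = c(1, 0, 0.8)))
  expect_equal(vector_magnitude(s)$vm, c(1, 1, 1))
})

test_that("spectral classifier detects in-band tones and rejects others", {
  in_band <- make_walking_stream(1.8, total_s = 300)
  sec <- classify_walking(in_band)
  expect_true(all(sec$is_walking))
  expect_equal(mean(sec$step_freq), 1.8, tolerance = 0.1 / 1.8)

  flat <- accel_stream(tibble::tibble(t = seq(0, 9.9, 0.1), x = 0, y = 0,
                                      z = 1))
  sec_flat <- classify_walking(flat)
  expect_true(all(!sec_flat$is_walking))
  expect_true(all(sec_flat$step_freq == 0))

  fast <- make_walking_stream(4.0, total_s = 300)
  expect_true(all(!classify_walking(fast)$is_walking))

  slow <- make_walking_stream(0.8, total_s = 300)
  expect_true(all(!classify_walking(slow)$is_walking))
})

test_that("bouts shorter than 2 s are marked non-walking", {
  t <- seq(0, 1.4, by = 0.1)
  s <- accel_stream(tibble::tibble(t = t, x = 0, y = 0,
                                   z = 1 + 0.3 * sin(2 * pi * 1.8 * t)))
  expect_true(all(!classify_walking(s)$is_walking))
})

test_that("daily step count applies exact duty-cycle proportionality", {
  sec <- tibble::tibble(second_start = 1:300, is_walking = TRUE,
                        step_freq = 2, peak_amplitude = 0.3)
  expect_identical(daily_step_count(sec, 10, 20), 1800L)   # 600 observed x 3
  expect_identical(daily_step_count(sec, 30, 30), 1200L)   # x 2 scheme
  none <- tibble::tibble(second_start = 1:10, is_walking = FALSE,
                         step_freq = 0, peak_amplitude = 0)
  expect_identical(daily_step_count(none), 0L)
})

test_that("cadence is 60 times the mean walking step frequency", {
  sec <- tibble::tibble(second_start = 1:10, is_walking = TRUE,
                        step_freq = 1.8, peak_amplitude = 0.3)
  expect_equal(daily_cadence(sec), 108)
  sec$step_freq <- rep(c(1.5, 2.1), 5)
  expect_equal(daily_cadence(sec), 108)
  expect_true(is.na(daily_cadence(
    tibble::tibble(second_start = 1, is_walking = FALSE, step_freq = 0,
                   peak_amplitude = 0))))
})

test_that("stride acceleration matches the sinusoid closed form 2A/pi", {
  for (A in c(0.15, 0.3)) {
    s <- make_walking_stream(1.8, A = A, total_s = 600)
    sec <- classify_walking(s)
    expect_equal(stride_acceleration(s, sec), 2 * A / pi, tolerance = 0.10)
  }
  # homogeneity: doubling A doubles the score (same peak structure)
  s1 <- make_walking_stream(1.8, A = 0.15, total_s = 300)
  s2 <- make_walking_stream(1.8, A = 0.30, total_s = 300)
  r <- stride_acceleration(s2, classify_walking(s2)) /
    stride_acceleration(s1, classify_walking(s1))
  expect_equal(r, 2, tolerance = 0.02)
})

test_that("steps match a brute-force zero-crossing oracle within 3%", {
  for (f in c(1.5, 1.8, 2.1)) {
    s <- make_walking_stream(f, total_s = 900)
    sec <- classify_walking(s)
    spectral <- daily_step_count(sec)
    oracle <- zero_crossing_steps(s) * 3
    expect_equal(spectral, oracle, tolerance = 0.03)
  }
})

test_that("adding walking seconds never decreases the step count", {
  s_long <- make_walking_stream(1.8, total_s = 600)
  s_short <- make_walking_stream(1.8, total_s = 300)
  expect_gte(daily_step_count(classify_walking(s_long)),
             daily_step_count(classify_walking(s_short)))
})

test_that("duty-cycled and continuous observation agree within 5%", {
  f <- 1.9; total <- 600
  duty <- make_walking_stream(f, total_s = total)
  t <- seq(0, total - 0.1, by = 0.1)
  cont <- accel_stream(tibble::tibble(t = t, x = 0, y = 0,
                                      z = 1 + 0.3 * sin(2 * pi * f * t)),
                       duty_on_s = 30, duty_off_s = 0)
  steps_duty <- daily_step_count(classify_walking(duty), 10, 20)
  steps_cont <- daily_step_count(classify_walking(cont), 30, 0)
  expect_equal(steps_duty, steps_cont, tolerance = 0.05)
})

test_that("daily gait summary splits by local calendar date", {
  # two walking blocks on consecutive UTC days
  d1 <- make_walking_stream(1.8, total_s = 300, t0 = 86400 - 300)
  d2 <- make_walking_stream(2.0, total_s = 300, t0 = 86400)
  s <- accel_stream(rbind(d1$samples, d2$samples), "T01")
  g <- gait_daily(s)
  expect_equal(nrow(g), 2)
  expect_equal(g$date, as.Date(c("1970-01-01", "1970-01-02")))
  expect_equal(g$cadence, c(108, 120), tolerance = 0.02)
  expect_true(all(g$steps_adjusted > 0))
})
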