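test_that("coverage counts minutes with any sample from either sensor", {
  # accel duty-cycled all day: every minute contains an on-bout
  tt <- gaitmob:::gps_fix_grid(10, 20, 0.5, 86400)  # 10/20 cycle sample times
  acc <- accel_stream(tibble::tibble(t = tt, x = 0, y = 0, z = 1))
  gps <- gps_trace(tibble::tibble(t = numeric(), lat = numeric(),
                                  lon = numeric(), accuracy = numeric()))
  expect_equal(coverage_minutes(acc, gps, as.Date("1970-01-01")), 1440L)

  # data only 00:00-08:00
  morning <- accel_stream(tibble::tibble(t = seq(0, 8 * 3600 - 1, 30),
                                         x = 0, y = 0, z = 1))
  expect_equal(coverage_minutes(morning, gps, as.Date("1970-01-01")), 480L)
  expect_equal(coverage_minutes(morning, gps, as.Date("1970-01-02")), 0L)
})

test_that("valid-day boundary is inclusive at 960 minutes", {
  d <- make_daily("P1", as.Date("2023-01-01") + 0:2,
                  coverage = c(960, 959, 1440))
  expect_equal(d$valid, c(TRUE, FALSE, TRUE))
})

test_that("adherence proportions follow valid and collected days", {
  d <- make_daily("P1", as.Date("2023-01-01") + 0:179,
                  coverage = rep(c(1000, 500, 0, 0), 45))
  a <- adherence_summary(d, 180)
  expect_equal(a$prop_collected, 0.5)
  expect_equal(a$prop_valid, 0.25)
  expect_true(a$prop_valid <= a$prop_collected)
  expect_error(adherence_summary(d, 0), "positive")
})

test_that("survey alignment averages valid days in a closed +/-10-day window", {
  dates <- as.Date("2023-01-01") + 0:40
  d <- make_daily("P1", dates, steps = seq_along(dates) * 100)
  sv <- tibble::tibble(participant_id = "P1", survey_day = 20,
                       date = as.Date("2023-01-21"))
  al <- align_to_surveys(d, sv)
  expect_equal(al$n_window_days, 21)
  expect_equal(al$steps_adjusted, mean(seq(11, 31) * 100))

  # only one valid day in the window
  d2 <- make_daily("P1", dates, steps = 1500,
                   coverage = c(rep(0, 20), 1440, rep(0, 20)))
  al2 <- align_to_surveys(d2, sv)
  expect_equal(al2$n_window_days, 1)
  expect_equal(al2$steps_adjusted, 1500)

  # no valid days: missing observation
  d3 <- make_daily("P1", dates, coverage = 100)
  al3 <- align_to_surveys(d3, sv)
  expect_equal(al3$n_window_days, 0)
  expect_true(is.na(al3$steps_adjusted))
})

test_that("window means are permutation-invariant and widen to the study mean", {
  set.seed(5)
  dates <- as.Date("2023-01-01") + 0:60
  d <- make_daily("P1", dates, steps = rpois(61, 2000),
                  coverage = sample(c(1440, 500), 61, replace = TRUE))
  sv <- tibble::tibble(participant_id = "P1", survey_day = 30,
                       date = as.Date("2023-01-31"))
  a1 <- align_to_surveys(d, sv)
  a2 <- align_to_surveys(d[sample(nrow(d)), ], sv)
  expect_equal(a1$steps_adjusted, a2$steps_adjusted)
  wide <- align_to_surveys(d, sv, window_days = 180)
  expect_equal(wide$steps_adjusted,
               mean(d$steps_adjusted[d$valid]))
})

test_that("first-fortnight means use valid days in study days 0-13", {
  dates <- as.Date("2023-01-01") + 0:29
  d <- make_daily("P1", dates, steps = 3000)
  ff <- first_fortnight_means(d)
  expect_equal(ff$steps_adjusted, 3000)
  expect_equal(ff$n_fortnight_days, 14)

  d2 <- make_daily("P1", dates, coverage = 100)
  expect_equal(nrow(first_fortnight_means(d2)), 0)
})
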