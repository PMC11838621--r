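small_cfg <- function(...) {
  cohort_config(n_participants = 2, study_days = 3, survey_days = c(0, 2),
                ...)
}

test_that("cohort simulation is deterministic in (config, seed)", {
  a <- simulate_cohort(small_cfg(), seed = 5)
  b <- simulate_cohort(small_cfg(), seed = 5)
  expect_identical(a$days, b$days)
  expect_identical(a$surveys, b$surveys)
  c_ <- simulate_cohort(small_cfg(), seed = 6)
  expect_false(identical(a$days$day_seed, c_$days$day_seed))
})

test_that("raw-day rendering is reproducible and respects coverage", {
  cfg <- small_cfg(valid_day_rate = 1, invalid_day_rate = 0)
  tr <- simulate_cohort(cfg, seed = 8)
  d <- tr$days[1, ]; p <- tr$participants[1, ]
  r1 <- generate_participant_day(d, p, cfg)
  r2 <- generate_participant_day(d, p, cfg)
  expect_identical(r1, r2)
  cutoff <- day_bounds(d$date)[1] + d$coverage_target_min * 60
  expect_true(all(r1$accel$t < cutoff))
  expect_true(all(r1$gps$t < cutoff))
  # missing days yield no data
  dm <- d; dm$status <- "missing"; dm$coverage_target_min <- 0
  expect_equal(nrow(generate_participant_day(dm, p, cfg)$accel), 0)
})

test_that("written cohorts have the documented layout and round-trip", {
  cfg <- small_cfg(valid_day_rate = 1, invalid_day_rate = 0)
  out1 <- file.path(tempdir(), "cohortA")
  out2 <- file.path(tempdir(), "cohortB")
  unlink(c(out1, out2), recursive = TRUE)
  write_cohort(cfg, out1, seed = 3)
  expect_true(dir.exists(file.path(out1, "P001", "accelerometer")))
  expect_true(dir.exists(file.path(out1, "P002", "gps")))
  expect_true(file.exists(file.path(out1, "surveys.csv")))
  truth <- readr::read_csv(file.path(out1, "truth.csv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), 6)  # 2 participants x 3 days
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_error(write_cohort(cfg, out1, seed = 3), "not empty")

  # same (config, seed): byte-identical raw files
  write_cohort(cfg, out2, seed = 3)
  f1 <- file.path(out1, "P001", "accelerometer",
                  list.files(file.path(out1, "P001", "accelerometer"))[1])
  f2 <- file.path(out2, "P001", "accelerometer",
                  list.files(file.path(out2, "P001", "accelerometer"))[1])
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("pipeline recovers the planted per-day truth", {
  cfg <- small_cfg(valid_day_rate = 1, invalid_day_rate = 0)
  tr <- simulate_cohort(cfg, seed = 21)
  p <- tr$participants[1, ]
  pdays <- tr$days[tr$days$participant_id == p$participant_id, ]
  acc <- list(); gps <- list()
  for (i in seq_len(nrow(pdays))) {
    raw <- generate_participant_day(pdays[i, ], p, cfg)
    acc[[i]] <- raw$accel; gps[[i]] <- raw$gps
  }
  stream <- accel_stream(dplyr::bind_rows(acc), p$participant_id)
  trace <- gps_trace(dplyr::bind_rows(gps), p$participant_id)
  g <- gait_daily(stream)
  m <- mobility_daily(trace)
  got <- dplyr::inner_join(g, m, by = c("participant_id", "date")) |>
    dplyr::inner_join(pdays, by = "date")
  expect_equal(nrow(got), 3)
  expect_equal(got$steps_adjusted, got$steps_true, tolerance = 0.03)
  expect_true(all(abs(got$cadence.x - got$cadence.y) <= 3))
  expect_true(all(abs(got$home_time_h.x - got$home_time_h.y) <= 0.2))
  expect_equal(got$distance_km.x, got$distance_km.y, tolerance = 0.01)
  expect_identical(as.integer(got$n_locations.x),
                   as.integer(got$n_locations.y))
})

test_that("default cohort truth sits at the published scale", {
  tr <- simulate_cohort(cohort_config(n_participants = 40, study_days = 60),
                        seed = 30)
  v <- tr$days[tr$days$status == "valid", ]
  expect_equal(mean(v$steps_true), 2235, tolerance = 0.10)
  expect_equal(mean(v$cadence), 105.5, tolerance = 0.05)
  expect_equal(mean(v$home_time_h), 14.9, tolerance = 0.15)
  expect_equal(mean(v$n_locations), 4.0, tolerance = 0.25)
  # planted valid-day rate
  expect_equal(mean(tr$days$status == "valid"), 0.741, tolerance = 0.05)
})

test_that("survey generation respects instrument ranges and links", {
  tr <- simulate_cohort(cohort_config(n_participants = 60, study_days = 1,
                                      survey_days = 0), seed = 31)
  sv <- tr$surveys
  expect_true(all(sv$ecog %in% 0:4))
  expect_true(all(sv$promis_raw >= 6 & sv$promis_raw <= 30))
  expect_equal(sv$promis_t, promis_raw_to_t(sv$promis_raw))
  expect_equal(mean(sv$promis_t), 44.4, tolerance = 0.1)
})
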