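test_that("planted PROMIS slope is recovered with sensible intervals", {
  set.seed(101)
  est <- cover <- numeric(20)
  for (r in 1:20) {
    d <- simulate_aligned_cohort()
    f <- fit_prom_association(d, "steps_adjusted", "promis_t")
    row <- f$terms[f$terms$term == "promis_t", ]
    est[r] <- row$estimate
    cover[r] <- row$ci_low <= 72.6 && 72.6 <= row$ci_high
    if (r == 1) {
      expect_lt(row$ci_low, row$estimate)
      expect_gt(row$ci_high, row$estimate)
      expect_true(row$p > 0 && row$p <= 1)
      expect_equal(f$n_participants, 85)
      expect_equal(f$n_obs, 340)
      # residual SD on the planted scale
      expect_equal(unname(f$varcomp["sd_resid"]), 400, tolerance = 0.2)
    }
  }
  expect_equal(mean(est), 72.6, tolerance = 0.05)
  expect_gte(mean(cover), 0.75)
})

test_that("categorical predictors use the best level as reference", {
  set.seed(102)
  d <- simulate_aligned_cohort(predictor = "ecog")
  f <- fit_prom_association(d, "steps_adjusted", "ecog")
  expect_false(any(grepl("ecog0", f$terms$term)))
  expect_true(any(grepl("ecog3", f$terms$term)))
  e3 <- f$terms[f$terms$term == "ecog3", ]
  expect_true(e3$ci_low <= -1837 && -1837 <= e3$ci_high)
  # row order of the input does not change estimates
  f2 <- fit_prom_association(d[sample(nrow(d)), ], "steps_adjusted", "ecog")
  expect_equal(f2$terms$estimate, f$terms$estimate, tolerance = 1e-8)
})

test_that("a constant predictor is reported as non-estimable", {
  set.seed(103)
  d <- simulate_aligned_cohort(predictor = "none")
  d$promis_t <- 50
  f <- fit_prom_association(d, "steps_adjusted", "promis_t")
  expect_equal(f$model_type, "non_estimable")
  expect_true(all(is.na(f$terms$estimate)))
})

test_that("zero slope variance falls back to the random-intercept fit", {
  set.seed(104)
  d <- simulate_aligned_cohort(sd_u1 = 0)
  f <- fit_prom_association(d, "steps_adjusted", "promis_t")
  expect_true(f$model_type %in% c("random_intercept", "random_slope_singular"))
  ref <- lme4::lmer(steps_adjusted ~ promis_t + (1 | participant_id),
                    data = dplyr::mutate(d, month = survey_day / 30.44),
                    REML = TRUE)
  if (f$model_type == "random_intercept") {
    expect_equal(unname(f$terms$estimate),
                 unname(lme4::fixef(ref)), tolerance = 1e-6)
  }
})

test_that("trend models report baseline and monthly change", {
  set.seed(105)
  b0 <- b1 <- numeric(20)
  for (r in 1:20) {
    d <- simulate_aligned_cohort(predictor = "none", intercept = 105.5,
                                 sd_u0 = 4, sd_u1 = 0.3, sd_resid = 3,
                                 trend_month = -0.23, outcome = "cadence")
    f <- fit_trend(d, "cadence")
    b0[r] <- f$terms$estimate[f$terms$term == "(Intercept)"]
    b1[r] <- f$terms$estimate[f$terms$term == "month"]
  }
  expect_equal(mean(b0), 105.5, tolerance = 0.02)
  expect_equal(mean(b1), -0.23, tolerance = 0.20)

  single <- simulate_aligned_cohort(survey_days = 0, predictor = "none")
  fs <- fit_trend(single, "steps_adjusted")
  expect_equal(fs$model_type, "non_estimable")
})

test_that("usage models run per outcome as fixed-effect regressions", {
  set.seed(106)
  n <- 40
  fortnight <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:n),
    steps_adjusted = rnorm(n, 2200, 500), cadence = rnorm(n, 105, 4),
    stride_accel = rnorm(n, 0.1, 0.01), home_time_h = rnorm(n, 15, 2),
    distance_km = rnorm(n, 70, 10), n_locations = rnorm(n, 4, 1),
    n_fortnight_days = 14)
  adher <- tibble::tibble(participant_id = sprintf("P%03d", 1:n),
                          days_collected = 150, days_valid = 120,
                          days_expected = 180,
                          prop_collected = runif(n, 0.6, 1),
                          prop_valid = runif(n, 0.5, 0.9))
  usage <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:n),
    usage_category = sample(c(">4h", "2-4h", "1-2h"), n, replace = TRUE))
  expect_warning(fits <- fit_usage_association(fortnight, adher, usage),
                 "dropped")
  expect_equal(length(fits), 8)
  expect_true(all(vapply(fits, function(f) f$model_type, "") == "fixed_only"))
  # planted null: most category CIs cover zero
  cat_terms <- tidy_fit(fits)
  cat_terms <- cat_terms[cat_terms$term != "(Intercept)", ]
  expect_gt(mean(cat_terms$ci_low <= 0 & 0 <= cat_terms$ci_high), 0.7)
})

test_that("tidy_fit produces a forest-plot-ready table", {
  set.seed(107)
  d <- simulate_aligned_cohort()
  f <- fit_prom_association(d, "steps_adjusted", "promis_t")
  td <- tidy_fit(f)
  expect_true(all(c("outcome", "predictor", "term", "estimate", "ci_low",
                    "ci_high", "p") %in% names(td)))
  expect_true(all(td$ci_low <= td$estimate & td$estimate <= td$ci_high))
})
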