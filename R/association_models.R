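DAYS_PER_MONTH <- 30.44

categorical_predictors <- c("ecog", "eq_mobility", "eq_selfcare", "eq_usual",
                            "eq_pain", "eq_anxiety", "usage_category")

# reference level = best health state for each categorical instrument
predictor_reference <- function(predictor) {
  switch(predictor,
         ecog = "0",
         usage_category = ">4h",
         "1")  # EQ-5D-5L items
}

new_gm_fit <- function(outcome, predictor, terms, n_obs, n_participants,
                       varcomp, model_type, note = NA_character_) {
  structure(
    list(outcome = outcome, predictor = predictor, terms = terms,
         n_obs = n_obs, n_participants = n_participants, varcomp = varcomp,
         model_type = model_type, note = note),
    class = "gm_fit"
  )
}

#' @export
print.gm_fit <- function(x, ...) {
  cat(sprintf("<gm_fit> %s ~ %s (%s; %d obs, %d participants)\n",
              x$outcome, x$predictor, x$model_type, x$n_obs,
              x$n_participants))
  print(x$terms)
  invisible(x)
}

#' Tidy a model fit (or list of fits) into a coefficient table
#'
#' One row per fixed-effect term: estimate, Wald 95% CI, p-value — the
#' forest-plot-ready export shape.
#'
#' @param fit a `gm_fit` or a list of them.
#' @return tibble with columns `outcome`, `predictor`, `term`, `estimate`,
#'   `ci_low`, `ci_high`, `p`, `model_type`.
#' @export
tidy_fit <- function(fit) {
  if (inherits(fit, "gm_fit")) fit <- list(fit)
  purrr::map_dfr(fit, function(f) {
    dplyr::mutate(f$terms, outcome = f$outcome, predictor = f$predictor,
                  model_type = f$model_type, .before = 1)
  })
}

wald_terms <- function(est, se) {
  z <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    ci_low = unname(est - qnorm(0.975) * se),
    ci_high = unname(est + qnorm(0.975) * se),
    p = unname(2 * pnorm(-abs(z)))
  )
}

# random-slope -> random-intercept -> plain-lm cascade
fit_lmm_cascade <- function(formula_slope, formula_int, formula_lm, data) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(formula_slope, data = data, REML = TRUE, control = ctrl))),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-4)) {
    return(list(fit = fit, model_type = "random_slope"))
  }
  fit_ri <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(formula_int, data = data, REML = TRUE, control = ctrl))),
    error = function(e) NULL)
  if (!is.null(fit_ri) && !lme4::isSingular(fit_ri, tol = 1e-4)) {
    return(list(fit = fit_ri, model_type = "random_intercept"))
  }
  # keep a singular mixed fit in preference to dropping random effects
  # entirely, unless lmer failed outright
  if (!is.null(fit)) return(list(fit = fit, model_type = "random_slope_singular"))
  if (!is.null(fit_ri)) return(list(fit = fit_ri, model_type = "random_intercept_singular"))
  list(fit = stats::lm(formula_lm, data = data), model_type = "fixed_only")
}

extract_varcomp <- function(fit) {
  if (!inherits(fit, "merMod")) {
    return(c(sd_intercept = NA_real_, sd_slope = NA_real_,
             sd_resid = stats::sigma(fit)))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_int <- vc$sdcor[vc$grp == "participant_id" & vc$var1 == "(Intercept)" &
                       is.na(vc$var2)]
  sd_slope <- vc$sdcor[vc$grp == "participant_id" & vc$var1 == "month" &
                         is.na(vc$var2)]
  c(sd_intercept = if (length(sd_int)) sd_int else NA_real_,
    sd_slope = if (length(sd_slope)) sd_slope else NA_real_,
    sd_resid = stats::sigma(fit))
}

prepare_predictor <- function(data, predictor) {
  if (predictor %in% categorical_predictors) {
    ref <- predictor_reference(predictor)
    f <- factor(as.character(data[[predictor]]))
    if (!ref %in% levels(f)) {
      stop("reference level '", ref, "' absent from predictor ", predictor)
    }
    data[[predictor]] <- stats::relevel(droplevels(f), ref = ref)
  }
  data
}

ensure_month <- function(data) {
  if (!"month" %in% names(data)) {
    if (!"survey_day" %in% names(data)) {
      stop("data needs a 'month' or 'survey_day' column")
    }
    data$month <- data$survey_day / DAYS_PER_MONTH
  }
  data
}

#' Fit a digital-measure ~ PROM longitudinal association model
#'
#' The spec'd model for Tables of PROM associations: the digital measure is
#' the outcome, the survey response the predictor, with a participant random
#' intercept and random slope on months since baseline to absorb repeated
#' measures:
#' `outcome = b0 + b * predictor + u0_i + u1_i * month + e`.
#' Estimated by REML with Wald 95% CIs. Categorical predictors (ECOG PS,
#' EQ-5D-5L items) use the best health state as reference; PROMIS T-scores
#' enter linearly. Singular random-slope fits fall back to a random
#' intercept only (flagged in `model_type`).
#'
#' @param aligned aligned observation table from [align_to_surveys()] joined
#'   with scored surveys (needs the outcome column, the predictor column,
#'   `participant_id`, and `survey_day` or `month`).
#' @param outcome one of the six digital-measure column names.
#' @param predictor predictor column name (`"promis_t"`, `"ecog"`, or an
#'   EQ-5D-5L item).
#' @return a `gm_fit`.
#' @export
fit_prom_association <- function(aligned, outcome, predictor) {
  data <- ensure_month(aligned)
  data <- data[stats::complete.cases(data[, c(outcome, predictor,
                                              "participant_id", "month")]), ]
  if (nrow(data) < 2 || length(unique(data$participant_id)) < 2) {
    stop("need at least 2 observations from at least 2 participants")
  }
  data <- prepare_predictor(data, predictor)

  pr <- data[[predictor]]
  constant <- if (is.factor(pr)) nlevels(droplevels(pr)) < 2 else
    (max(pr) - min(pr)) == 0
  if (constant) {
    return(new_gm_fit(outcome, predictor,
                      wald_terms(setNames(NA_real_, predictor),
                                 setNames(NA_real_, predictor)),
                      nrow(data), length(unique(data$participant_id)),
                      c(sd_intercept = NA, sd_slope = NA, sd_resid = NA),
                      "non_estimable",
                      note = "predictor constant; slope non-estimable"))
  }

  f_slope <- stats::as.formula(
    paste0("`", outcome, "` ~ `", predictor, "` + (1 + month | participant_id)"))
  f_int <- stats::as.formula(
    paste0("`", outcome, "` ~ `", predictor, "` + (1 | participant_id)"))
  f_lm <- stats::as.formula(paste0("`", outcome, "` ~ `", predictor, "`"))
  res <- fit_lmm_cascade(f_slope, f_int, f_lm, data)

  est <- lme4::fixef(res$fit)
  if (!inherits(res$fit, "merMod")) est <- stats::coef(res$fit)
  se <- sqrt(diag(as.matrix(stats::vcov(res$fit))))
  new_gm_fit(outcome, predictor, wald_terms(est, se), nrow(data),
             length(unique(data$participant_id)), extract_varcomp(res$fit),
             res$model_type)
}

#' Fit a baseline + monthly-change trend model
#'
#' `outcome = b0 + b1 * month + u0_i + u1_i * month + e`; `b0` is the
#' baseline cohort level and `b1` the average change per month
#' (study day / 30.44).
#'
#' @param data aligned or daily table with the outcome, `participant_id`,
#'   and `survey_day`/`study_day`/`month`.
#' @param outcome digital-measure column name.
#' @return a `gm_fit` with terms `(Intercept)` (baseline) and `month`.
#' @export
fit_trend <- function(data, outcome) {
  if (!"month" %in% names(data) && "study_day" %in% names(data)) {
    data$month <- data$study_day / DAYS_PER_MONTH
  }
  data <- ensure_month(data)
  data <- data[stats::complete.cases(data[, c(outcome, "participant_id",
                                              "month")]), ]
  if (nrow(data) < 2 || length(unique(data$participant_id)) < 2) {
    stop("need at least 2 observations from at least 2 participants")
  }
  one_tp <- all(tapply(data$month, data$participant_id,
                       function(m) length(unique(m))) == 1)
  if (one_tp && length(unique(data$month)) == 1) {
    return(new_gm_fit(outcome, "month",
                      wald_terms(c(`(Intercept)` = NA_real_, month = NA_real_),
                                 c(`(Intercept)` = NA_real_, month = NA_real_)),
                      nrow(data), length(unique(data$participant_id)),
                      c(sd_intercept = NA, sd_slope = NA, sd_resid = NA),
                      "non_estimable",
                      note = "single time point; slope non-estimable"))
  }
  f_slope <- stats::as.formula(
    paste0("`", outcome, "` ~ month + (1 + month | participant_id)"))
  f_int <- stats::as.formula(
    paste0("`", outcome, "` ~ month + (1 | participant_id)"))
  f_lm <- stats::as.formula(paste0("`", outcome, "` ~ month"))
  res <- fit_lmm_cascade(f_slope, f_int, f_lm, data)
  est <- if (inherits(res$fit, "merMod")) lme4::fixef(res$fit) else
    stats::coef(res$fit)
  se <- sqrt(diag(as.matrix(stats::vcov(res$fit))))
  new_gm_fit(outcome, "month", wald_terms(est, se), nrow(data),
             length(unique(data$participant_id)), extract_varcomp(res$fit),
             res$model_type)
}

#' Fit smartphone-use association models
#'
#' One model per outcome — the two data-quality proportions and each
#' first-fortnight digital-measure mean — with the self-reported smartphone
#' use category as predictor (reference: more than 4 hours a day). With one
#' row per participant the random effects are degenerate, so these are
#' ordinary least-squares fits reported in the same shape.
#'
#' @param fortnight output of [first_fortnight_means()].
#' @param adherence output of [adherence_summary()].
#' @param usage tibble `participant_id`, `usage_category`.
#' @return named list of `gm_fit` objects.
#' @export
fit_usage_association <- function(fortnight, adherence, usage) {
  df <- usage |>
    dplyr::left_join(adherence, by = "participant_id") |>
    dplyr::left_join(fortnight, by = "participant_id")
  f <- droplevels(factor(as.character(df$usage_category),
                         levels = usage_levels))
  if (">4h" %in% levels(f)) {
    f <- stats::relevel(f, ref = ">4h")
  } else {
    warning("reference usage category '>4h' has no participants; ",
            "using '", levels(f)[1], "' as reference")
  }
  df$usage_category <- f
  missing_lv <- setdiff(usage_levels, levels(f))
  if (length(missing_lv)) {
    warning("usage categories with no participants dropped: ",
            paste(missing_lv, collapse = ", "))
  }
  outcomes <- c("prop_collected", "prop_valid", measure_cols)
  fits <- lapply(outcomes, function(oc) {
    dat <- df[stats::complete.cases(df[, c(oc, "usage_category")]), ]
    fit <- stats::lm(stats::as.formula(paste0("`", oc, "` ~ usage_category")),
                     data = dat)
    est <- stats::coef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    keep <- !is.na(est)
    new_gm_fit(oc, "usage_category", wald_terms(est[keep], se[keep]),
               nrow(dat), nrow(dat),
               c(sd_intercept = NA, sd_slope = NA, sd_resid = stats::sigma(fit)),
               "fixed_only")
  })
  names(fits) <- outcomes
  fits
}
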