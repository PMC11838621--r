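usage_levels <- c(">4h", "2-4h", "1-2h", "30m-1h", "<30m")

#' Score the EQ-5D-5L descriptive system
#'
#' Five items (mobility, self-care, usual activities, pain/discomfort,
#' anxiety/depression), each leveled 1 (best) to 5 (worst); the total is the
#' simple sum, range 5-25. Items are analysed individually as categorical
#' predictors; the total is used for range checks and summaries (no country
#' value set is applied).
#'
#' @param items integer vector of length 5, each in 1..5.
#' @return integer total in 5..25.
#' @export
score_eq5d <- function(items) {
  items <- as.numeric(items)
  if (length(items) != 5 || anyNA(items) ||
      any(items != round(items) | items < 1 | items > 5)) {
    stop("EQ-5D-5L items must be five integers in 1..5")
  }
  as.integer(sum(items))
}

#' Validate a patient-reported ECOG performance status
#'
#' @param value candidate score; 0 ("fully active") to 4 ("completely
#'   disabled").
#' @return the validated integer.
#' @export
validate_ecog <- function(value) {
  v <- as.numeric(value)
  if (length(v) != 1 || is.na(v) || v != round(v) || v < 0 || v > 4) {
    stop("ECOG PS must be a single integer in 0..4")
  }
  as.integer(v)
}

#' Bundled raw-to-T conversion table for PROMIS PF 6b
#'
#' A synthetic, strictly monotone stand-in for the official sum-score lookup
#' (which is licensed separately and not bundled): a linear map of raw scores
#' 6-30 onto T-scores 22.0-60.4. Replace with the official table via the
#' `table` argument of [promis_raw_to_t()] for real analyses.
#'
#' @return tibble with columns `raw` (6..30) and `t`.
#' @export
promis_t_table_synthetic <- function() {
  path <- system.file("extdata", "promis_pf6b_t_synthetic.csv",
                      package = "gaitmob")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Convert PROMIS PF 6b raw scores to T-scores
#'
#' Sum-score table lookup; the table must be strictly monotone in `raw` so
#' better physical function always maps to a higher T-score.
#'
#' @param raw integer raw scores in 6..30.
#' @param table conversion tibble with columns `raw`, `t`; defaults to the
#'   bundled synthetic table.
#' @return numeric T-scores.
#' @export
promis_raw_to_t <- function(raw, table = NULL) {
  if (is.null(table)) table <- promis_t_table_synthetic()
  if (any(diff(table$t[order(table$raw)]) < 0)) {
    stop("conversion table must be monotone non-decreasing in raw")
  }
  raw <- as.numeric(raw)
  if (anyNA(raw) || any(raw != round(raw) | raw < 6 | raw > 30)) {
    stop("PROMIS PF 6b raw scores must be integers in 6..30")
  }
  table$t[match(raw, table$raw)]
}

#' Read and score a survey CSV
#'
#' Expects columns `participant_id, survey_day, date, ecog, eq_mobility,
#' eq_selfcare, eq_usual, eq_pain, eq_anxiety, promis_raw, usage_category`.
#' Validates all ranges, computes `eq5d_total` and `promis_t`, and orders the
#' smartphone-use categories with "more than 4 hours" first (the reference
#' level of the usage models).
#'
#' @param path survey CSV path.
#' @param t_table optional PROMIS conversion table (see [promis_raw_to_t()]).
#' @return scored survey tibble.
#' @export
read_surveys <- function(path, t_table = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "survey_day", "date", "ecog", "eq_mobility",
            "eq_selfcare", "eq_usual", "eq_pain", "eq_anxiety", "promis_raw",
            "usage_category")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("survey CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  df$ecog <- vapply(df$ecog, validate_ecog, integer(1))
  eq <- as.matrix(df[, c("eq_mobility", "eq_selfcare", "eq_usual",
                         "eq_pain", "eq_anxiety")])
  df$eq5d_total <- apply(eq, 1, score_eq5d)
  df$promis_t <- promis_raw_to_t(df$promis_raw, t_table)
  if (!all(df$usage_category %in% usage_levels)) {
    stop("unknown usage_category; expected one of: ",
         paste(usage_levels, collapse = ", "))
  }
  df$usage_category <- factor(df$usage_category, levels = usage_levels)
  df$date <- as.Date(df$date)
  tibble::as_tibble(df)
}
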