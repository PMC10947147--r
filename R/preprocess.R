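#' Assign the 12-level age-sex category
#'
#' Categories are the interaction of sex with the six age groups 35-44,
#' 45-54, 55-64, 65-74, 75-84 and 85+ (closed 10-year bins, open-ended top
#' bin).  The reference category is men aged 35-44.  Vectorised.
#'
#' @param sex character vector of `"M"`/`"F"`.
#' @param age_years integer ages, all >= 35.
#' @return factor with the 12 canonical levels (age ascending, men before
#'   women), e.g. `"M_35-44"`, `"F_85+"`.
#' @export
assign_age_sex_category <- function(sex, age_years) {
  check_flag(all(sex %in% SEXES), "sex must be 'M' or 'F'")
  check_flag(all(!is.na(age_years)) && all(age_years >= 35),
             "age_years must all be >= 35 (ages below the target population are rejected)")
  grp <- AGE_GROUPS[findInterval(age_years, c(AGE_LOWER, Inf))]
  factor(paste(sex, grp, sep = "_"), levels = AGESEX_LEVELS)
}

#' Prorate the HADS depression subscale
#'
#' Seven items scored 0-3 (total range 0-21).  Respondents with four or more
#' missing items are scored missing; with up to three missing items the sum
#' of completed items is prorated to the 7-item scale:
#' `sum(completed) * 7 / n_completed`.  The prorated score is kept as an
#' unrounded real.
#'
#' @param items a length-7 vector, or an n x 7 matrix/data.frame, of item
#'   scores in `{0, 1, 2, 3}` with `NA` for missing.
#' @return numeric score(s) in `[0, 21]`, `NA` where >= 4 items are missing.
#' @export
prorate_hads <- function(items) {
  m <- if (is.null(dim(items))) matrix(as.numeric(items), nrow = 1) else as.matrix(items)
  check_flag(ncol(m) == 7, "HADS depression requires exactly 7 items")
  vals <- m[!is.na(m)]
  check_flag(all(vals %in% 0:3), "HADS items must be integers 0-3")
  n_complete <- rowSums(!is.na(m))
  score <- unname(rowSums(m, na.rm = TRUE) * 7 / n_complete)
  score[n_complete < 4] <- NA_real_
  score
}

#' Body mass index from self-reported weight and height
#'
#' @param weight_kg positive weights in kg (`NA` allowed).
#' @param height_m positive heights in metres (`NA` allowed).
#' @return BMI in kg/m^2; `NA` where either input is missing.
#' @export
compute_bmi <- function(weight_kg, height_m) {
  check_flag(all(weight_kg > 0, na.rm = TRUE) && all(height_m > 0, na.rm = TRUE),
             "weight and height must be positive")
  weight_kg / height_m^2
}

#' Derive analysis records from raw respondent rows
#'
#' Maps raw survey rows to the modelling variables: the 12-level age-sex
#' category, logical outcome indicators, the prorated HADS depression score
#' and BMI.  No filtering happens here; see [filter_complete_cases()].
#'
#' @param respondents data.frame in the `respondents.csv` layout.
#' @return data.frame with respondent_id, lsoa_code, agesex, chronic_pain,
#'   high_impact, depression_score, bmi.
#' @export
make_analysis_records <- function(respondents) {
  req <- c("respondent_id", "lsoa_code", "sex", "age_years",
           "chronic_pain", "high_impact")
  missing_cols <- setdiff(req, names(respondents))
  check_flag(length(missing_cols) == 0, "respondents table lacks column(s): %s",
             paste(missing_cols, collapse = ", "))
  hads_cols <- paste0("hads_d", 1:7)
  dep <- if (all(hads_cols %in% names(respondents)))
    prorate_hads(respondents[hads_cols]) else NA_real_
  bmi <- if (all(c("weight_kg", "height_m") %in% names(respondents)))
    compute_bmi(respondents$weight_kg, respondents$height_m) else NA_real_
  data.frame(
    respondent_id = respondents$respondent_id,
    lsoa_code = respondents$lsoa_code,
    agesex = assign_age_sex_category(respondents$sex, respondents$age_years),
    chronic_pain = as.logical(respondents$chronic_pain),
    high_impact = as.logical(respondents$high_impact),
    depression_score = dep,
    bmi = bmi,
    stringsAsFactors = FALSE)
}

#' Complete-case filter
#'
#' Keeps exactly the records with no missing value in the required fields
#' (order preserved).  The main analysis requires age, sex (both folded into
#' `agesex`) and the two pain outcomes; sensitivity analyses add
#' `depression_score` and/or `bmi`.
#'
#' @param records analysis records ([make_analysis_records()]).
#' @param required character vector of field names that must be non-missing.
#' @return list with `kept` (data.frame) and `dropped` (integer count).
#' @export
filter_complete_cases <- function(records,
                                  required = c("agesex", "chronic_pain", "high_impact")) {
  unknown <- setdiff(required, names(records))
  check_flag(length(unknown) == 0, "unknown field(s) in required: %s",
             paste(unknown, collapse = ", "))
  keep <- if (length(required) == 0) rep(TRUE, nrow(records))
          else stats::complete.cases(records[required])
  list(kept = records[keep, , drop = FALSE], dropped = sum(!keep))
}

#' Crude prevalence with raw counts
#'
#' Numerator, denominator and percent prevalence of an outcome, either for
#' one stratum (via a predicate) or tabulated by a grouping column.
#' Computation is at full precision; display rounding (whole percent, as in
#' crude survey tables) is left to the caller or [format_crude_table()].
#'
#' @param records analysis records.
#' @param outcome name of a logical outcome column.
#' @param stratum optional predicate `function(records) -> logical` or a
#'   logical vector selecting the stratum; rejected if it selects nobody.
#' @param by optional column name to tabulate by (e.g. `"agesex"`) instead
#'   of a single stratum.
#' @return data.frame with columns (group,) numerator, denominator, percent.
#' @export
crude_prevalence <- function(records, outcome = "chronic_pain",
                             stratum = NULL, by = NULL) {
  check_flag(outcome %in% names(records), "unknown outcome column '%s'", outcome)
  y <- records[[outcome]]
  if (!is.null(by)) {
    check_flag(by %in% names(records), "unknown grouping column '%s'", by)
    g <- records[[by]]
    den <- tapply(!is.na(y), g, sum)
    num <- tapply(y, g, sum, na.rm = TRUE)
    out <- data.frame(group = names(den), numerator = as.integer(num),
                      denominator = as.integer(den),
                      percent = 100 * as.integer(num) / as.integer(den),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  sel <- if (is.null(stratum)) rep(TRUE, nrow(records))
         else if (is.function(stratum)) stratum(records) else as.logical(stratum)
  y <- y[sel]
  check_flag(sum(!is.na(y)) > 0, "stratum is empty: crude prevalence undefined")
  data.frame(numerator = sum(y, na.rm = TRUE), denominator = sum(!is.na(y)),
             percent = 100 * sum(y, na.rm = TRUE) / sum(!is.na(y)))
}
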