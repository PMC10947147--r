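#' Ground-truth parameters for the synthetic data-generating process
#'
#' The generator draws each individual's chronic-pain indicator from a
#' Bernoulli with probability `invlogit(b0 + b_agesex + b_imd + b_rural + u_j)`
#' where `u_j ~ N(0, sigma2_u)` is the LSOA random intercept.  The
#' high-impact indicator is then a second Bernoulli, conditional on chronic
#' pain, with an age-sex-specific conditional probability; this construction
#' guarantees the definitional nesting (high-impact implies chronic).
#'
#' Default log-odds offsets are chosen so crude prevalences rise with age,
#' are higher in women, fall with affluence and are lower in rural areas,
#' approximating the crude pattern of the emulating survey (reference cell
#' men 35-44 near 23% crude once the deprivation mix is averaged over,
#' women 85+ around +1.4 log-odds, most-deprived decile about +1.05
#' log-odds against decile 10).  The exact values are generator configuration, not published
#' estimates.  `sigma2_u` defaults to 0.1432, the between-LSOA variance
#' implied by a 4.17% latent-threshold variance partition.
#'
#' @param intercept log-odds of chronic pain in the reference cell (men
#'   35-44, IMD decile 10, urban, average covariates).
#' @param beta_agesex named log-odds offsets for the 11 non-reference
#'   age-sex categories.
#' @param beta_imd named log-odds offsets for IMD deciles 1..9 (reference:
#'   decile 10, most affluent).
#' @param beta_rural log-odds offset for rural LSOAs.
#' @param sigma2_u between-LSOA variance of the random intercept (log-odds
#'   squared); must be >= 0.
#' @param beta_depression,beta_bmi optional log-odds per unit of the centred
#'   covariate; `NULL` leaves the covariate out of the generating model.
#' @param high_impact_given_chronic named probability, per age-sex category,
#'   that a person with chronic pain has high-impact chronic pain.
#' @return an object of class `true_parameters`.
#' @export
true_parameters <- function(intercept = -1.70,
                            beta_agesex = c(
                              "F_35-44" = -0.12,
                              "M_45-54" = 0.26, "F_45-54" = 0.45,
                              "M_55-64" = 0.41, "F_55-64" = 0.59,
                              "M_65-74" = 0.63, "F_65-74" = 0.72,
                              "M_75-84" = 0.84, "F_75-84" = 1.01,
                              "M_85+" = 0.41, "F_85+" = 1.37),
                            beta_imd = c(
                              "1" = 1.05, "2" = 0.90, "3" = 0.75, "4" = 0.62,
                              "5" = 0.50, "6" = 0.40, "7" = 0.30, "8" = 0.20,
                              "9" = 0.10),
                            beta_rural = -0.30,
                            sigma2_u = 0.1432,
                            beta_depression = NULL,
                            beta_bmi = NULL,
                            high_impact_given_chronic = c(
                              "M_35-44" = 0.25, "F_35-44" = 0.34,
                              "M_45-54" = 0.30, "F_45-54" = 0.34,
                              "M_55-64" = 0.34, "F_55-64" = 0.43,
                              "M_65-74" = 0.45, "F_65-74" = 0.41,
                              "M_75-84" = 0.52, "F_75-84" = 0.55,
                              "M_85+" = 0.59, "F_85+" = 0.53)) {
  truth <- structure(
    list(intercept = intercept, beta_agesex = beta_agesex, beta_imd = beta_imd,
         beta_rural = beta_rural, sigma2_u = sigma2_u,
         beta_depression = beta_depression, beta_bmi = beta_bmi,
         high_impact_given_chronic = high_impact_given_chronic),
    class = "true_parameters")
  validate_true_parameters(truth)
  truth
}

validate_true_parameters <- function(truth) {
  check_flag(truth$sigma2_u >= 0, "sigma2_u must be non-negative")
  nonref <- setdiff(AGESEX_LEVELS, AGESEX_REFERENCE)
  check_flag(setequal(names(truth$beta_agesex), nonref),
             "beta_agesex must name exactly the 11 non-reference age-sex categories")
  check_flag(setequal(names(truth$beta_imd), as.character(1:9)),
             "beta_imd must name IMD deciles 1..9 (decile 10 is the reference)")
  check_flag(setequal(names(truth$high_impact_given_chronic), AGESEX_LEVELS) &&
               all(truth$high_impact_given_chronic >= 0 & truth$high_impact_given_chronic <= 1),
             "high_impact_given_chronic must give a probability for all 12 age-sex categories")
  invisible(truth)
}

# fixed-effect part of the true linear predictor for a set of cells
true_linear_predictor <- function(truth, agesex, imd_decile, rural_flag) {
  b_as <- c(setNames(0, AGESEX_REFERENCE), truth$beta_agesex)[as.character(agesex)]
  b_imd <- c(truth$beta_imd, "10" = 0)[as.character(imd_decile)]
  truth$intercept + unname(b_as) + unname(b_imd) + truth$beta_rural * rural_flag
}

#' True LSOA prevalence implied by the generator (the estimand)
#'
#' Population-cell-weighted mean of the generating cell probabilities, using
#' the realized random intercepts.  This is the quantity the MRP pipeline is
#' asked to recover in simulation tests.
#'
#' @param geography a [generate_geography()] result.
#' @param truth a [true_parameters()] object.
#' @param drawn_effects named numeric: the realized random intercept (log-odds)
#'   for every LSOA, as returned by [generate_respondents()].
#' @param outcome `"chronic_pain"` or `"high_impact"`; high-impact truth is
#'   the chronic-pain cell probability times the conditional probability.
#' @return data.frame with `lsoa_code` and `true_prevalence` (proportion).
#' @export
true_prevalence <- function(geography, truth, drawn_effects,
                            outcome = c("chronic_pain", "high_impact")) {
  outcome <- match.arg(outcome)
  validate_true_parameters(truth)
  pop <- merge(geography$population, geography$profiles, by = "lsoa_code", sort = FALSE)
  missing_u <- setdiff(unique(pop$lsoa_code), names(drawn_effects))
  if (length(missing_u) > 0)
    stop_painscape("drawn_effects missing LSOA(s): %s",
                   paste(utils::head(missing_u, 5), collapse = ", "))
  agesex <- paste(pop$sex, pop$age_group, sep = "_")
  p <- invlogit(true_linear_predictor(truth, agesex, pop$imd_decile, pop$rural_flag) +
                  drawn_effects[pop$lsoa_code])
  if (outcome == "high_impact")
    p <- p * truth$high_impact_given_chronic[agesex]
  num <- tapply(p * pop$count, pop$lsoa_code, sum)
  den <- tapply(pop$count, pop$lsoa_code, sum)
  check_flag(all(den > 0), "every LSOA must have positive population")
  codes <- geography$profiles$lsoa_code
  data.frame(lsoa_code = codes,
             true_prevalence = as.numeric(num[codes] / den[codes]),
             row.names = NULL, stringsAsFactors = FALSE)
}
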