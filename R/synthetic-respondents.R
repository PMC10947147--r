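#' Generate synthetic survey respondents
#'
#' Simulates the survey's sampling chain and the outcome-generating process.
#' Each LSOA receives a random intercept `u_j ~ N(0, sigma2_u)`; each
#' resident is independently included with probability
#' `sampling_fraction * frame_coverage * response_rate`; each included
#' respondent's chronic-pain indicator is Bernoulli with probability
#' `invlogit(true linear predictor + u_j)`, and the high-impact indicator is
#' a second Bernoulli conditional on chronic pain, so high-impact never
#' occurs without chronic pain.  HADS depression items (seven items scored
#' 0-3), self-reported weight and height are attached, and missingness is
#' injected completely at random at the configured rates.
#'
#' The default sampling chain (0.21 x 0.146 x 0.519, with ~5% missing
#' outcome data) reproduces the emulated survey's arithmetic: a 21% sample
#' of an approximately 15%-coverage practice frame over a 275,391-person
#' region yields ~8,500 invitations, ~4,400 responses and ~4,150 complete
#' cases.
#'
#' @param geography a [generate_geography()] result.
#' @param truth a [true_parameters()] object.
#' @param sampling_fraction probability in (0, 1] that a frame member is
#'   sampled (the survey's stated sample rate).
#' @param frame_coverage proportion of the 35+ population on the sample
#'   frame.
#' @param response_rate proportion of sampled persons who return a usable
#'   questionnaire.
#' @param missingness list of MCAR rates: `chronic`, `high_impact` (outcome
#'   items), `hads_item` (per depression item), `anthropometry` (weight and,
#'   independently, height).
#' @param seed integer seed.
#' @return an object of class `pain_survey`: list with `respondents` (one
#'   row per respondent: respondent_id, lsoa_code, sex, age_years,
#'   chronic_pain, high_impact, hads_d1..hads_d7, weight_kg, height_m; NA =
#'   missing) and `u` (named vector of the drawn random intercepts for every
#'   LSOA, for truth-tracking).
#' @export
generate_respondents <- function(geography, truth = true_parameters(),
                                 sampling_fraction = 0.21,
                                 frame_coverage = 0.146,
                                 response_rate = 0.519,
                                 missingness = list(chronic = 0.030,
                                                    high_impact = 0.025,
                                                    hads_item = 0.030,
                                                    anthropometry = 0.060),
                                 seed = 1L) {
  validate_true_parameters(truth)
  check_flag(sampling_fraction > 0 && sampling_fraction <= 1,
             "sampling_fraction must be in (0, 1]")
  check_flag(frame_coverage > 0 && frame_coverage <= 1 &&
               response_rate > 0 && response_rate <= 1,
             "frame_coverage and response_rate must be in (0, 1]")
  set.seed(derive_seed(seed, 202L))

  profiles <- geography$profiles
  u <- setNames(rnorm(nrow(profiles), 0, sqrt(truth$sigma2_u)), profiles$lsoa_code)

  p_include <- sampling_fraction * frame_coverage * response_rate
  pop <- merge(geography$population, profiles, by = "lsoa_code", sort = FALSE)
  n_cell <- rbinom(nrow(pop), pop$count, p_include)
  idx <- rep(seq_len(nrow(pop)), n_cell)
  n <- length(idx)

  lsoa_code <- pop$lsoa_code[idx]
  sex <- pop$sex[idx]
  age_group <- pop$age_group[idx]
  lo <- AGE_LOWER[match(age_group, AGE_GROUPS)]
  # uniform within closed 10-year bins; 85+ tails off geometrically
  age_years <- ifelse(age_group == "85+",
                      85L + pmin(rgeom(n, 0.25), 14L),
                      lo + sample.int(10L, n, replace = TRUE) - 1L)
  agesex <- paste(sex, age_group, sep = "_")

  # depression score (0-21) and anthropometry, generated before outcomes so
  # optional covariate effects can enter the linear predictor
  dep_score <- pmax(0L, pmin(21L, round(rnorm(n, 4.5, 3.5))))
  height_m <- round(ifelse(sex == "M", rnorm(n, 1.75, 0.07), rnorm(n, 1.62, 0.065)), 2)
  weight_kg <- round(ifelse(sex == "M", rnorm(n, 84, 14), rnorm(n, 72, 14)), 1)
  height_m <- pmax(height_m, 1.3)
  weight_kg <- pmax(weight_kg, 35)

  lp <- true_linear_predictor(truth, agesex, pop$imd_decile[idx], pop$rural_flag[idx]) +
    u[lsoa_code]
  if (!is.null(truth$beta_depression)) lp <- lp + truth$beta_depression * (dep_score - 4.5)
  if (!is.null(truth$beta_bmi)) lp <- lp + truth$beta_bmi * (weight_kg / height_m^2 - 27.5)
  chronic <- rbinom(n, 1, invlogit(lp))
  high_impact <- chronic * rbinom(n, 1, truth$high_impact_given_chronic[agesex])

  # split the depression score over 7 items (each 0-3): floor share plus one
  # extra point on a random subset of items
  base <- dep_score %/% 7L
  remainder <- dep_score %% 7L
  items <- matrix(rep(base, 7L), nrow = n, ncol = 7L)
  bump <- which(remainder > 0)
  for (i in bump) {
    pick <- sample.int(7L, remainder[i])
    items[i, pick] <- items[i, pick] + 1L
  }

  # MCAR missingness
  chronic[runif(n) < missingness$chronic] <- NA
  high_impact[runif(n) < missingness$high_impact] <- NA
  items[matrix(runif(n * 7L) < missingness$hads_item, n, 7L)] <- NA
  weight_kg[runif(n) < missingness$anthropometry] <- NA
  height_m[runif(n) < missingness$anthropometry] <- NA

  respondents <- data.frame(
    respondent_id = sprintf("R%06d", seq_len(n)),
    lsoa_code = lsoa_code, sex = sex, age_years = as.integer(age_years),
    chronic_pain = as.integer(chronic), high_impact = as.integer(high_impact),
    stringsAsFactors = FALSE)
  colnames(items) <- paste0("hads_d", 1:7)
  respondents <- cbind(respondents, as.data.frame(items))
  respondents$weight_kg <- weight_kg
  respondents$height_m <- height_m

  structure(list(respondents = respondents, u = u, truth = truth,
                 p_include = p_include),
            class = "pain_survey")
}

#' @export
print.pain_survey <- function(x, ...) {
  cat(sprintf("Synthetic survey: %d respondents in %d LSOAs\n",
              nrow(x$respondents), length(unique(x$respondents$lsoa_code))))
  invisible(x)
}

#' Write the synthetic tables to CSV
#'
#' Writes `lsoa_profiles.csv`, `population.csv`, `ethnicity.csv`,
#' `respondents.csv` and (for test/ground-truth use) `truth.csv` holding the
#' generating parameters and the per-LSOA true prevalence of both outcomes.
#'
#' @param geography a [generate_geography()] result.
#' @param survey a [generate_respondents()] result.
#' @param dir output directory (created if absent).
#' @param config_hash,seed optional provenance recorded in the CSV header
#'   comment.
#' @return invisibly, the paths written.
#' @export
write_synthetic_data <- function(geography, survey, dir,
                                 config_hash = NULL, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("lsoa_profiles.csv", "population.csv",
                            "ethnicity.csv", "respondents.csv", "truth.csv"))
  write_pain_csv(geography$profiles, paths[1], config_hash, seed)
  write_pain_csv(geography$population, paths[2], config_hash, seed)
  write_pain_csv(geography$ethnicity, paths[3], config_hash, seed)
  write_pain_csv(survey$respondents, paths[4], config_hash, seed)

  truth <- survey$truth
  par_df <- data.frame(
    parameter = c("intercept",
                  paste0("agesex_", names(truth$beta_agesex)),
                  paste0("imd_", names(truth$beta_imd)),
                  "rural", "sigma2_u"),
    value = c(truth$intercept, unname(truth$beta_agesex),
              unname(truth$beta_imd), truth$beta_rural, truth$sigma2_u),
    stringsAsFactors = FALSE)
  tp_c <- true_prevalence(geography, truth, survey$u, "chronic_pain")
  tp_h <- true_prevalence(geography, truth, survey$u, "high_impact")
  truth_df <- rbind(
    par_df,
    data.frame(parameter = paste0("u_", names(survey$u)), value = unname(survey$u)),
    data.frame(parameter = paste0("prev_chronic_", tp_c$lsoa_code),
               value = tp_c$true_prevalence),
    data.frame(parameter = paste0("prev_high_impact_", tp_h$lsoa_code),
               value = tp_h$true_prevalence))
  write_pain_csv(truth_df, paths[5], config_hash, seed)
  invisible(paths)
}
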