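# Shared fixtures, memoised so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# a compact two-LA region for unit tests
small_geography_spec <- function(n_lsoas = 40L,
                                 populations = c(14000, 10000),
                                 rural_fraction = c(0.1, 0.5)) {
  n_a <- ceiling(n_lsoas / 2)
  geography_spec(
    n_lsoas = n_lsoas,
    local_authorities = data.frame(
      name = c("LA-A", "LA-B"),
      n_lsoas = c(n_a, n_lsoas - n_a),
      n_msoas = pmax(1L, c(n_a, n_lsoas - n_a) %/% 5L),
      population_35plus = populations),
    imd_decile_distribution = rbind(
      c(0.25, 0.20, 0.15, 0.10, 0.08, 0.07, 0.05, 0.04, 0.03, 0.03),
      c(0.03, 0.04, 0.06, 0.10, 0.13, 0.15, 0.15, 0.14, 0.11, 0.09)),
    rural_fraction = rural_fraction,
    ethnicity = list(typical_mean = c(0.945, 0.025, 0.010, 0.007, 0.013),
                     diverse_mean = c(0.700, 0.220, 0.040, 0.015, 0.025),
                     concentration = 400,
                     diverse_prob = c(0.15, 0.03)))
}

# one-LA wrapper where every coefficient can be forced to a constant
flat_truth <- function(intercept = 0, sigma2_u = 0, beta_rural = 0) {
  true_parameters(
    intercept = intercept,
    beta_agesex = setNames(rep(0, 11),
                           setdiff(painscape:::AGESEX_LEVELS, "M_35-44")),
    beta_imd = setNames(rep(0, 9), as.character(1:9)),
    beta_rural = beta_rural,
    sigma2_u = sigma2_u)
}

no_missing <- list(chronic = 0, high_impact = 0, hads_item = 0, anthropometry = 0)

small_region <- function() memo("small_region", {
  geo <- generate_geography(small_geography_spec(), seed = 11)
  survey <- generate_respondents(geo, seed = 11, sampling_fraction = 0.6,
                                 frame_coverage = 0.25, response_rate = 1,
                                 missingness = no_missing)
  records <- filter_complete_cases(make_analysis_records(survey$respondents))$kept
  list(geo = geo, survey = survey, records = records)
})

small_fit_chronic <- function() memo("small_fit_chronic", {
  r <- small_region()
  fit_approximate(build_design(r$records, r$geo, model_spec("chronic_pain")))
})

# full-size study region (298 LSOAs, ~4,100 complete cases) used by the
# acceptance checks
study_region <- function() memo("study_region", {
  geo <- generate_geography(seed = 42)
  survey <- generate_respondents(geo, seed = 42)
  records <- filter_complete_cases(make_analysis_records(survey$respondents))$kept
  list(geo = geo, survey = survey, records = records)
})

study_fit_chronic <- function() memo("study_fit_chronic", {
  r <- study_region()
  fit_approximate(build_design(r$records, r$geo, model_spec("chronic_pain")))
})

study_fit_high_impact <- function() memo("study_fit_high_impact", {
  r <- study_region()
  fit_approximate(build_design(r$records, r$geo, model_spec("high_impact")))
})

# parameter-recovery simulation at study scale: 20 survey replicates over a
# fixed geography, each fitted by MCMC; used by the recovery and bias checks
recovery_sim <- function() memo("recovery_sim", {
  geo <- generate_geography(seed = 42)
  truth <- true_parameters()
  true_beta <- c(setNames(truth$beta_agesex,
                          painscape:::agesex_colname(names(truth$beta_agesex))),
                 setNames(truth$beta_imd, paste0("imd_", 1:9)),
                 rural = truth$beta_rural)
  n_rep <- 20
  cover <- bias <- matrix(NA, n_rep, 21,
                          dimnames = list(NULL, names(true_beta)))
  s2 <- numeric(n_rep)
  extras <- NULL
  for (r in seq_len(n_rep)) {
    survey <- generate_respondents(geo, truth, sampling_fraction = 0.21,
                                   frame_coverage = 0.139, response_rate = 1,
                                   missingness = no_missing, seed = 1000 + r)
    rec <- filter_complete_cases(make_analysis_records(survey$respondents))$kept
    d <- build_design(rec, geo, model_spec("chronic_pain"))
    fit <- suppressWarnings(fit_mcmc(d, model_spec(
      "chronic_pain", mcmc = list(chains = 2, burn = 500, iter = 1000, seed = r),
      min_ess = 50)))
    cf <- fit$coefficients
    i <- match(names(true_beta), cf$parameter)
    cover[r, ] <- cf$q2.5[i] <= true_beta & true_beta <= cf$q97.5[i]
    bias[r, ] <- cf$mean[i] - true_beta
    s2[r] <- median(fit$sigma2_draws)
    if (r == 1) {
      cells <- predict_cell_probabilities(fit, geo)
      est <- aggregate_prevalence(cells, geo, "lsoa")
      tp <- true_prevalence(geo, truth, survey$u)
      pops <- tapply(geo$population$count, geo$population$lsoa_code,
                     sum)[tp$lsoa_code]
      extras <- list(
        cor_lsoa = cor(est$prevalence_percent,
                       tp$true_prevalence[match(est$geography_id, tp$lsoa_code)]),
        region_est = aggregate_prevalence(cells, geo, "region")$prevalence_percent,
        region_truth = 100 * sum(tp$true_prevalence * pops) / sum(pops),
        n = nrow(rec))
    }
  }
  c(list(cover = cover, bias = bias, s2 = s2, truth = truth), extras)
})

# hand-built degenerate posterior in the full 22-column design layout
toy_fit <- function(geography, intercept_draws = 0, u_draws = NULL,
                    sigma2 = 0) {
  terms <- c("(Intercept)",
             painscape:::agesex_colname(setdiff(painscape:::AGESEX_LEVELS, "M_35-44")),
             paste0("imd_", 1:9), "rural")
  S <- length(intercept_draws)
  beta <- matrix(0, S, length(terms), dimnames = list(NULL, terms))
  beta[, 1] <- intercept_draws
  codes <- geography$profiles$lsoa_code
  u <- u_draws %||% matrix(0, S, length(codes), dimnames = list(NULL, codes))
  fit <- painscape:::new_pain_fit("toy",
                                  list(lsoa_levels = colnames(u),
                                       centring = numeric(0),
                                       outcome = "chronic_pain"),
                                  beta, u, rep(sigma2, S))
  fit$term_names <- terms
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a
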