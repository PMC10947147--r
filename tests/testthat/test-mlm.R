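test_that("the design matrix uses treatment coding in the documented order", {
  r <- small_region()
  d <- build_design(r$records, r$geo, model_spec("chronic_pain"))
  expect_equal(ncol(d$X), 22)  # intercept + 11 agesex + 9 IMD + rural
  expect_equal(colnames(d$X)[1:3], c("(Intercept)", "agesex_F_35_44", "agesex_M_45_54"))
  expect_equal(colnames(d$X)[13:22], c(paste0("imd_", 1:9), "rural"))

  # a reference respondent (man 35-44, IMD 10, urban) has all dummies zero
  prof <- r$geo$profiles
  ref_lsoas <- prof$lsoa_code[prof$imd_decile == 10 & prof$rural_flag == 0]
  i <- which(r$records$agesex == "M_35-44" & r$records$lsoa_code %in% ref_lsoas)[1]
  expect_false(is.na(i))  # the fixture draws thousands of records; the reference cell is populated
  expect_equal(unname(d$X[i, -1]), rep(0, 21))

  expect_error(build_design(transform(r$records[1:5, ], lsoa_code = "NOPE"),
                            r$geo, model_spec()), "unknown LSOA")
})

test_that("centred covariates add columns with mean zero and travel with the fit", {
  r <- small_region()
  sens <- filter_complete_cases(r$records, c("agesex", "chronic_pain", "high_impact",
                                             "depression_score", "bmi"))$kept
  d <- build_design(sens, r$geo, model_spec("chronic_pain",
                                            covariates = c("depression", "bmi")))
  expect_equal(ncol(d$X), 24)
  expect_equal(mean(d$X[, "depression_c"]), 0, tolerance = 1e-10)
  expect_equal(mean(d$X[, "bmi_c"]), 0, tolerance = 1e-10)
  expect_equal(unname(d$centring["depression"]), mean(sens$depression_score))
  fit <- fit_approximate(d)
  expect_equal(fit$centring, d$centring)
})

test_that("the Polya-Gamma sampler matches the PG(1,z) mean", {
  set.seed(99)
  for (z in c(0, 1, 3)) {
    draws <- painscape:::.rpg(40000L, z)
    mu <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
    expect_lt(abs(mean(draws) - mu), 4 * sd(draws) / sqrt(length(draws)))
    expect_true(all(draws > 0))
  }
})

test_that("MCMC draws are reproducible, shaped correctly and agree with the fast fitter", {
  r <- small_region()
  d <- build_design(r$records, r$geo, model_spec("chronic_pain"))
  spec <- model_spec("chronic_pain",
                     mcmc = list(chains = 2, burn = 300, iter = 700, seed = 3),
                     min_ess = 20)
  fit <- suppressWarnings(fit_mcmc(d, spec))
  expect_equal(dim(fit$beta_draws), c(1400, 22))
  expect_equal(ncol(fit$u_draws), length(d$lsoa_levels))
  expect_true(all(fit$sigma2_draws >= 0))
  expect_true(all(c("ess", "rhat") %in% names(fit$diagnostics$table)))

  fit2 <- suppressWarnings(fit_mcmc(d, spec))
  expect_identical(fit$beta_draws, fit2$beta_draws)
  expect_identical(fit$sigma2_draws, fit2$sigma2_draws)

  approx <- fit_approximate(d)
  expect_lt(max(abs(coef(fit) - coef(approx))), 0.1)
})

test_that("random intercepts exist exactly for represented LSOAs", {
  r <- small_region()
  sub <- r$records[r$records$lsoa_code %in% unique(r$records$lsoa_code)[1:8], ]
  d <- build_design(sub, r$geo, model_spec("chronic_pain"))
  fit <- fit_approximate(d)
  expect_setequal(colnames(fit$u_draws), unique(sub$lsoa_code))
})

test_that("degenerate designs are rejected or flagged", {
  r <- small_region()
  one <- r$records[r$records$lsoa_code == r$records$lsoa_code[1], ]
  d1 <- build_design(one, r$geo, model_spec("chronic_pain"))
  expect_error(fit_mcmc(d1), "single LSOA")
  expect_error(fit_approximate(d1), "single LSOA")

  # separation: a category whose outcomes are all 1 draws a warning
  sep <- r$records[1:200, ]
  sep$chronic_pain[sep$agesex == "F_85+"] <- TRUE
  if (sum(sep$agesex == "F_85+") > 0) {
    d2 <- build_design(sep, r$geo, model_spec("chronic_pain"))
    expect_warning(
      fit_mcmc(d2, model_spec("chronic_pain",
                              mcmc = list(chains = 1, burn = 20, iter = 30, seed = 1),
                              min_ess = 1)),
      "separation")
  }
})

test_that("a zero-variance truth is recovered at the boundary", {
  geo <- generate_geography(small_geography_spec(populations = c(30000, 25000)),
                            seed = 21)
  survey <- generate_respondents(geo, true_parameters(sigma2_u = 0),
                                 sampling_fraction = 0.3, frame_coverage = 0.3,
                                 response_rate = 1, missingness = no_missing,
                                 seed = 21)
  rec <- filter_complete_cases(make_analysis_records(survey$respondents))$kept
  d <- build_design(rec, geo, model_spec("chronic_pain"))
  approx <- fit_approximate(d)
  expect_lt(approx$sigma2_draws, 0.02)
  mc <- suppressWarnings(
    fit_mcmc(d, model_spec("chronic_pain",
                           mcmc = list(chains = 2, burn = 300, iter = 600, seed = 2),
                           min_ess = 20)))
  expect_lt(median(mc$sigma2_draws), 0.05)
})

test_that("fixed effects are recovered without material bias", {
  rs <- recovery_sim()
  mean_bias <- colMeans(rs$bias)
  agesex <- grep("^agesex_", names(mean_bias))
  # individual-level contrasts are unbiased to within Monte-Carlo error
  expect_lt(max(abs(mean_bias[agesex])), 0.05)
  # area-level terms (IMD, rural) compete with the LSOA random intercept at
  # ~27 respondents per area and show a modest finite-sample attenuation;
  # they stay well inside the posterior uncertainty of a single fit
  expect_lt(max(abs(mean_bias[-agesex])), 0.15)
})

test_that("the variance partition coefficient follows the latent-threshold formula", {
  expect_equal(compute_vpc(0), 0)
  expect_equal(compute_vpc(pi^2 / 3), 0.5)
  expect_equal(compute_vpc(0.1432), 0.0417, tolerance = 1e-3)
  expect_error(compute_vpc(-0.1), "non-negative")
  # monotone increasing and bounded in [0, 1)
  v <- compute_vpc(seq(0, 50, by = 0.5))
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0 & v < 1))
})
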