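test_that("default geography reproduces the regional structure and is deterministic", {
  geo <- generate_geography(seed = 1)
  expect_equal(nrow(geo$profiles), 298)
  counts <- table(geo$profiles$la_name)
  expect_equal(counts[["Stoke-on-Trent"]], 159)
  expect_equal(counts[["Newcastle-under-Lyme"]], 80)
  expect_equal(counts[["Staffordshire Moorlands"]], 59)
  expect_false(anyDuplicated(geo$profiles$lsoa_code) > 0)
  expect_true(all(geo$profiles$imd_decile %in% 1:10))
  expect_true(all(geo$profiles$rural_flag %in% 0:1))

  # LA population totals are conserved exactly under apportionment
  pop <- merge(geo$population, geo$profiles, by = "lsoa_code")
  tot <- tapply(pop$count, pop$la_name, sum)
  expect_equal(tot[["Stoke-on-Trent"]], 136718)
  expect_equal(tot[["Newcastle-under-Lyme"]], 74399)
  expect_equal(tot[["Staffordshire Moorlands"]], 64274)
  expect_equal(nrow(geo$population), 298 * 12)

  props <- as.matrix(geo$ethnicity[, -1])
  expect_true(all(abs(rowSums(props) - 1) < 1e-9))
  expect_gt(mean(props[, "white"]), 0.85)

  expect_identical(geo, generate_geography(seed = 1))
  expect_false(identical(geo$profiles$imd_decile,
                         generate_geography(seed = 2)$profiles$imd_decile))
})

test_that("a one-LSOA geography conserves its population across the 12 cells", {
  spec <- geography_spec(
    n_lsoas = 1L,
    local_authorities = data.frame(name = "A", n_lsoas = 1L, n_msoas = 1L,
                                   population_35plus = 1200),
    imd_decile_distribution = matrix(rep(0.1, 10), 1),
    rural_fraction = 0,
    ethnicity = list(typical_mean = c(0.945, 0.025, 0.010, 0.007, 0.013),
                     diverse_mean = c(0.70, 0.22, 0.04, 0.015, 0.025),
                     concentration = 400, diverse_prob = 0))
  geo <- generate_geography(spec, seed = 3)
  expect_equal(nrow(geo$population), 12)
  expect_equal(sum(geo$population$count), 1200)
})

test_that("invalid geography specifications are rejected with a message", {
  la <- data.frame(name = "A", n_lsoas = 1L, n_msoas = 1L, population_35plus = -5)
  expect_error(geography_spec(n_lsoas = 1L, local_authorities = la,
                              imd_decile_distribution = matrix(rep(0.1, 10), 1),
                              rural_fraction = 0,
                              ethnicity = list(typical_mean = c(1, 0, 0, 0, 0),
                                               diverse_mean = c(1, 0, 0, 0, 0),
                                               concentration = 1, diverse_prob = 0)),
               "positive")
  expect_error(geography_spec(local_authorities = data.frame()), "non-empty")
})

test_that("null truth yields ~50% prevalence and the outcomes nest", {
  geo <- generate_geography(small_geography_spec(), seed = 5)
  survey <- generate_respondents(geo, flat_truth(intercept = 0),
                                 sampling_fraction = 0.5, frame_coverage = 1,
                                 response_rate = 1, missingness = no_missing,
                                 seed = 5)
  y <- survey$respondents$chronic_pain
  n <- length(y)
  expect_gt(n, 9000)
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / n))
  # definitional nesting: high-impact only among chronic
  expect_true(all(survey$respondents$high_impact <= y))
})

test_that("a negative rural effect lowers rural prevalence by the logistic arithmetic", {
  geo <- generate_geography(small_geography_spec(rural_fraction = c(0.5, 0.5)),
                            seed = 6)
  survey <- generate_respondents(geo, flat_truth(intercept = 0, beta_rural = -0.5),
                                 sampling_fraction = 0.5, frame_coverage = 1,
                                 response_rate = 1, missingness = no_missing,
                                 seed = 6)
  r <- survey$respondents
  rural_lsoas <- geo$profiles$lsoa_code[geo$profiles$rural_flag == 1]
  is_rural <- r$lsoa_code %in% rural_lsoas
  p_rural <- mean(r$chronic_pain[is_rural])
  p_urban <- mean(r$chronic_pain[!is_rural])
  expect_lt(p_rural, p_urban)
  expect_lt(abs(p_rural - plogis(-0.5)), 3 * sqrt(0.25 / sum(is_rural)))
  expect_lt(abs(p_urban - 0.5), 3 * sqrt(0.25 / sum(!is_rural)))
})

test_that("the default sampling chain lands near the emulated complete-case count", {
  r <- study_region()
  expect_lt(abs(nrow(r$records) - 4162) / 4162, 0.10)
  # every LSOA got a drawn random effect, sampled or not
  expect_setequal(names(r$survey$u), r$geo$profiles$lsoa_code)
})

test_that("respondent generation is reproducible and validates its inputs", {
  geo <- generate_geography(small_geography_spec(n_lsoas = 10L,
                                                 populations = c(2000, 1500)),
                            seed = 2)
  s1 <- generate_respondents(geo, seed = 9)
  s2 <- generate_respondents(geo, seed = 9)
  expect_identical(s1$respondents, s2$respondents)
  expect_identical(s1$u, s2$u)
  expect_error(generate_respondents(geo, sampling_fraction = 0), "sampling_fraction")
  expect_error(generate_respondents(geo, sampling_fraction = 1.2), "sampling_fraction")
})

test_that("true_prevalence is the population-weighted cell mean", {
  # constant probability: every LSOA returns it
  geo <- generate_geography(small_geography_spec(n_lsoas = 6L,
                                                 populations = c(2000, 1500)),
                            seed = 4)
  truth <- flat_truth(intercept = qlogis(0.3))
  u0 <- setNames(rep(0, 6), geo$profiles$lsoa_code)
  tp <- true_prevalence(geo, truth, u0)
  expect_equal(tp$true_prevalence, rep(0.3, 6), tolerance = 1e-12)

  # two equal-size cells at 0.2 and 0.4 average to 0.3
  geo2 <- geo
  geo2$profiles <- geo$profiles[1, ]
  geo2$population <- data.frame(lsoa_code = geo$profiles$lsoa_code[1],
                                sex = c("M", "F"), age_group = "35-44",
                                count = c(100, 100))
  truth2 <- flat_truth(intercept = qlogis(0.2))
  truth2$beta_agesex["F_35-44"] <- qlogis(0.4) - qlogis(0.2)
  tp2 <- true_prevalence(geo2, truth2, u0[1])
  expect_equal(tp2$true_prevalence, 0.3, tolerance = 1e-12)

  # arbitrary three-cell case against a hand-rolled weighted sum
  geo3 <- geo2
  geo3$population <- data.frame(lsoa_code = geo$profiles$lsoa_code[1],
                                sex = c("M", "F", "M"),
                                age_group = c("35-44", "35-44", "45-54"),
                                count = c(120, 80, 50))
  truth3 <- flat_truth(intercept = -0.4)
  truth3$beta_agesex["F_35-44"] <- 0.7
  truth3$beta_agesex["M_45-54"] <- -0.3
  u3 <- setNames(0.25, geo$profiles$lsoa_code[1])
  imd3 <- geo3$profiles$imd_decile[1]
  rural3 <- geo3$profiles$rural_flag[1]
  expected <- sum(c(120, 80, 50) * plogis(c(-0.4, 0.3, -0.7) + 0.25)) / 250
  tp3 <- true_prevalence(geo3, truth3, u3)
  expect_equal(tp3$true_prevalence, expected, tolerance = 1e-12)

  expect_error(true_prevalence(geo, truth, u0[-1]), "SYN00001")
})
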