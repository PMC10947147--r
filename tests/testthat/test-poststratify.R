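test_that("a null model predicts one half everywhere and responds to u monotonically", {
  r <- small_region()
  fit0 <- toy_fit(r$geo)
  cells <- predict_cell_probabilities(fit0, r$geo)
  expect_equal(cells$probability, rep(0.5, nrow(cells)), tolerance = 1e-12)

  # larger random intercept, all else equal, strictly larger probability
  codes <- r$geo$profiles$lsoa_code
  u <- matrix(0, 1, length(codes), dimnames = list(NULL, codes))
  u[1, codes[2]] <- 0.8
  fit_u <- toy_fit(r$geo, u_draws = u)
  p <- predict_cell_probability(fit_u, r$geo, codes[2], "M_35-44")
  q <- predict_cell_probability(fit_u, r$geo, codes[1], "M_35-44")
  expect_gt(p, q)
  expect_equal(q, 0.5)
})

test_that("cell probability is the posterior mean of invlogit over draws", {
  r <- small_region()
  fit3 <- toy_fit(r$geo, intercept_draws = c(-1, 0, 2))
  p <- predict_cell_probability(fit3, r$geo, r$geo$profiles$lsoa_code[1], "M_35-44")
  expect_equal(p, mean(plogis(c(-1, 0, 2))), tolerance = 1e-12)
  # distinct from the inverse logit of the mean coefficient
  expect_lt(p, plogis(mean(c(-1, 0, 2))))
})

test_that("unrepresented LSOAs follow the chosen effect policy", {
  r <- small_region()
  sub <- r$records[r$records$lsoa_code %in% unique(r$records$lsoa_code)[1:10], ]
  fit <- fit_approximate(build_design(sub, r$geo, model_spec("chronic_pain")))
  cells0 <- predict_cell_probabilities(fit, r$geo, "posterior_mean_zero_fill")
  expect_false(anyNA(cells0$probability))
  cells1a <- predict_cell_probabilities(fit, r$geo, "integrate_draws", seed = 1)
  cells1b <- predict_cell_probabilities(fit, r$geo, "integrate_draws", seed = 1)
  expect_identical(cells1a, cells1b)
})

test_that("aggregation is a population-weighted mean with exact conservation", {
  r <- small_region()
  fitp <- toy_fit(r$geo, intercept_draws = qlogis(0.37))
  for (lv in c("lsoa", "la", "region")) {
    est <- aggregate_prevalence(predict_cell_probabilities(fitp, r$geo), r$geo, lv)
    expect_equal(est$prevalence_percent, rep(37, nrow(est)), tolerance = 1e-9)
  }

  cells <- predict_cell_probabilities(small_fit_chronic(), r$geo)
  lsoa <- aggregate_prevalence(cells, r$geo, "lsoa")
  la <- aggregate_prevalence(cells, r$geo, "la")
  reg <- aggregate_prevalence(cells, r$geo, "region")
  pop <- r$geo$population
  pop$agesex <- paste(pop$sex, pop$age_group, sep = "_")
  mm <- merge(pop, cells, by = c("lsoa_code", "agesex"))
  expect_equal(reg$estimated_count, sum(mm$count * mm$probability), tolerance = 1e-9)
  expect_equal(sum(la$estimated_count), reg$estimated_count, tolerance = 1e-9)
  expect_equal(sum(lsoa$estimated_count), reg$estimated_count, tolerance = 1e-9)
  expect_true(all(lsoa$prevalence_percent >= 0 & lsoa$prevalence_percent <= 100))

  # two equal-size cells at 0.2 and 0.4 aggregate to 30%
  toy_cells <- data.frame(lsoa_code = r$geo$profiles$lsoa_code[1],
                          agesex = c("M_35-44", "F_35-44"),
                          probability = c(0.2, 0.4))
  toy_geo <- r$geo
  toy_geo$profiles <- r$geo$profiles[1, ]
  toy_geo$population <- data.frame(lsoa_code = r$geo$profiles$lsoa_code[1],
                                   sex = c("M", "F"), age_group = "35-44",
                                   count = c(500, 500))
  expect_equal(aggregate_prevalence(toy_cells, toy_geo, "lsoa")$prevalence_percent, 30)
})

test_that("ethnicity correction blends factors by proportions", {
  r <- small_region()
  lsoa <- aggregate_prevalence(predict_cell_probabilities(small_fit_chronic(), r$geo),
                               r$geo, "lsoa")

  # an all-White region is unchanged
  geo_white <- r$geo
  geo_white$ethnicity[painscape:::ETHNIC_GROUPS] <-
    matrix(rep(c(1, 0, 0, 0, 0), each = nrow(geo_white$ethnicity)), ncol = 5)
  cw <- apply_ethnicity_correction(lsoa, geo_white)
  expect_equal(cw$prevalence_percent, lsoa$prevalence_percent, tolerance = 1e-12)
  expect_true(all(cw$corrected))

  # half White, half Black at 10% baseline: 10 * (0.5*1.0 + 0.5*1.2) = 11
  geo_half <- geo_white
  geo_half$ethnicity$white <- 0.5
  geo_half$ethnicity$black <- 0.5
  base <- lsoa
  base$prevalence_percent <- 10
  base$estimated_count <- base$population * 0.1
  ch <- apply_ethnicity_correction(base, geo_half)
  expect_equal(ch$prevalence_percent, rep(11, nrow(ch)), tolerance = 1e-12)
  expect_equal(ch$multiplier, rep(1.1, nrow(ch)), tolerance = 1e-12)

  # shared ethnicity profile preserves the ordering of estimates
  expect_equal(order(cw$prevalence_percent), order(lsoa$prevalence_percent))

  # correction truncates at 100% with a warning
  big <- base
  big$prevalence_percent <- 95
  geo_black <- geo_white
  geo_black$ethnicity$white <- 0
  geo_black$ethnicity$black <- 1
  expect_warning(cb <- apply_ethnicity_correction(big, geo_black), "truncated")
  expect_true(all(cb$prevalence_percent <= 100))

  # invalid proportions are rejected
  geo_bad <- geo_white
  geo_bad$ethnicity$white[1] <- 0.8
  expect_error(apply_ethnicity_correction(lsoa, geo_bad), "sum to 1")
})

test_that("subgroup prevalence reduces to weighted means per group", {
  r <- small_region()
  fitp <- toy_fit(r$geo, intercept_draws = qlogis(0.25))
  cells <- predict_cell_probabilities(fitp, r$geo)
  for (g in c("agesex", "imd_decile", "rurality")) {
    sg <- subgroup_prevalence(cells, r$geo, g)
    expect_equal(sg$prevalence_percent, rep(25, nrow(sg)), tolerance = 1e-9)
  }

  # hand-computed two-group rurality split
  cells2 <- cells
  rural_lsoas <- r$geo$profiles$lsoa_code[r$geo$profiles$rural_flag == 1]
  cells2$probability <- ifelse(cells2$lsoa_code %in% rural_lsoas, 0.1, 0.3)
  sg2 <- subgroup_prevalence(cells2, r$geo, "rurality")
  expect_equal(sg2$prevalence_percent[sg2$group == "rural"], 10, tolerance = 1e-9)
  expect_equal(sg2$prevalence_percent[sg2$group == "urban"], 30, tolerance = 1e-9)
})

test_that("a generated deprivation gradient is recovered across IMD deciles", {
  r <- study_region()
  cells <- predict_cell_probabilities(study_fit_chronic(), r$geo)
  sg <- subgroup_prevalence(cells, r$geo, "imd_decile")
  rho <- cor(as.integer(sg$group), sg$prevalence_percent, method = "spearman")
  expect_lte(rho, -0.9)  # prevalence falls with affluence, as generated
})
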