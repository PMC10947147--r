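test_that("age-sex categorisation maps bins and boundaries correctly", {
  expect_equal(as.character(assign_age_sex_category("M", 35)), "M_35-44")
  expect_equal(as.character(assign_age_sex_category("F", 85)), "F_85+")
  expect_equal(as.character(assign_age_sex_category("F", 44)), "F_35-44")
  expect_equal(as.character(assign_age_sex_category("F", 45)), "F_45-54")
  expect_equal(as.character(assign_age_sex_category("M", 103)), "M_85+")
  expect_error(assign_age_sex_category("M", 34), "35")
  expect_error(assign_age_sex_category("X", 40), "sex")

  # exhaustive sweep: total on its domain, exactly 12 categories realised
  grid <- expand.grid(sex = c("M", "F"), age = 35:110)
  cats <- assign_age_sex_category(grid$sex, grid$age)
  expect_false(anyNA(cats))
  expect_equal(sort(unique(as.character(cats))), sort(painscape:::AGESEX_LEVELS))
  expect_equal(nlevels(cats), 12)
})

test_that("HADS proration follows the missing-item rule", {
  expect_equal(prorate_hads(rep(2, 7)), 14)
  expect_equal(prorate_hads(c(3, 3, 3, 1, NA, NA, NA)), 10 * 7 / 4)  # = 17.5
  expect_true(is.na(prorate_hads(c(3, 3, 3, NA, NA, NA, NA))))
  expect_error(prorate_hads(c(4, 0, 0, 0, 0, 0, 0)), "0-3")
  expect_error(prorate_hads(rep(1, 6)), "7 items")

  # equals the plain sum when complete; monotone in each item; capped at 21
  set.seed(1)
  m <- matrix(sample(0:3, 70, replace = TRUE), 10, 7)
  expect_equal(prorate_hads(m), rowSums(m))
  base <- c(1, 1, 1, NA, NA, 2, 0)
  for (i in which(!is.na(base))) {
    bumped <- base
    bumped[i] <- base[i] + 1
    expect_gt(prorate_hads(bumped), prorate_hads(base))
  }
  expect_lte(max(prorate_hads(matrix(3, 5, 7))), 21)
  expect_lte(prorate_hads(c(3, 3, 3, 3, NA, NA, NA)), 21)
})

test_that("BMI is weight over height squared with missing propagation", {
  expect_equal(compute_bmi(80, 2.0), 20)
  expect_equal(compute_bmi(72, 1.8), 72 / 1.8^2)
  expect_true(is.na(compute_bmi(NA, 1.7)))
  expect_true(is.na(compute_bmi(70, NA)))
  expect_error(compute_bmi(-70, 1.7), "positive")
})

test_that("complete-case filtering counts, preserves order and is idempotent", {
  rec <- data.frame(respondent_id = sprintf("R%02d", 1:10),
                    lsoa_code = "L1",
                    agesex = "M_35-44",
                    chronic_pain = c(TRUE, NA, FALSE, TRUE, NA, TRUE, FALSE, NA, TRUE, TRUE),
                    high_impact = FALSE,
                    depression_score = c(NA, 3, 4, NA, 1, 2, 9, 0, NA, 5),
                    bmi = 25)
  fc <- filter_complete_cases(rec, "chronic_pain")
  expect_equal(nrow(fc$kept), 7)
  expect_equal(fc$dropped, 3)
  expect_equal(fc$kept$respondent_id, rec$respondent_id[!is.na(rec$chronic_pain)])

  # empty requirement is the identity
  expect_equal(nrow(filter_complete_cases(rec, character(0))$kept), 10)

  # idempotent
  fc2 <- filter_complete_cases(fc$kept, "chronic_pain")
  expect_identical(fc2$kept, fc$kept)
  expect_equal(fc2$dropped, 0)

  # the sensitivity sample is a subset of the main-analysis sample
  main <- filter_complete_cases(rec, c("chronic_pain", "high_impact"))$kept
  sens <- filter_complete_cases(rec, c("chronic_pain", "high_impact",
                                       "depression_score", "bmi"))$kept
  expect_true(all(sens$respondent_id %in% main$respondent_id))

  expect_error(filter_complete_cases(rec, "no_such_field"), "unknown field")
})

test_that("crude prevalence reproduces published worked examples", {
  mk <- function(n, k) data.frame(chronic_pain = rep(c(TRUE, FALSE), c(k, n - k)))
  w3544 <- crude_prevalence(mk(198, 41))
  expect_equal(w3544$numerator, 41)
  expect_equal(w3544$denominator, 198)
  expect_equal(round(w3544$percent), 21)
  m85 <- crude_prevalence(mk(71, 22))
  expect_equal(round(m85$percent), 31)
  expect_equal(crude_prevalence(mk(50, 0))$percent, 0)
  expect_error(crude_prevalence(mk(10, 5), stratum = rep(FALSE, 10)), "empty")
})

test_that("analysis records derive model variables from raw rows", {
  r <- small_region()
  rec <- make_analysis_records(r$survey$respondents)
  expect_true(all(c("agesex", "chronic_pain", "high_impact",
                    "depression_score", "bmi") %in% names(rec)))
  i <- which(!is.na(rec$depression_score))[1]
  raw <- r$survey$respondents[i, paste0("hads_d", 1:7)]
  expect_equal(rec$depression_score[i], prorate_hads(raw))
  expect_error(make_analysis_records(data.frame(respondent_id = "a")), "lacks column")
})
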