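#' Default multiplicative ethnicity correction factors
#'
#' Prevalence ratios relative to White populations, per outcome, used to
#' adjust poststratified estimates for ethnic diversity under-represented in
#' the survey sample: chronic pain — Asian excluding Chinese 1.1, Black 1.2,
#' Chinese 0.9, Mixed/multiple 1.0; high-impact chronic pain — 1.2, 1.5,
#' 0.8, 1.1 respectively; White fixed at 1.0 for both.
#'
#' @param chronic_pain,high_impact named numeric overrides (names from
#'   `white`, `asian_excl_chinese`, `black`, `chinese`, `mixed_multiple`).
#' @return matrix with one row per ethnic group, one column per outcome.
#' @export
correction_factors <- function(chronic_pain = NULL, high_impact = NULL) {
  f <- cbind(
    chronic_pain = c(white = 1.0, asian_excl_chinese = 1.1, black = 1.2,
                     chinese = 0.9, mixed_multiple = 1.0),
    high_impact = c(white = 1.0, asian_excl_chinese = 1.2, black = 1.5,
                    chinese = 0.8, mixed_multiple = 1.1))
  if (!is.null(chronic_pain)) f[names(chronic_pain), "chronic_pain"] <- chronic_pain
  if (!is.null(high_impact)) f[names(high_impact), "high_impact"] <- high_impact
  check_flag(all(f > 0), "correction factors must be positive")
  check_flag(all(f["white", ] == 1), "the White factor is fixed at 1.0 by definition")
  f
}

# cell-level fixed-effect design for one (agesex, imd, rural) combination,
# in the fitted model's column order; continuous covariates sit at their
# centring means, i.e. contribute zero
cell_design_matrix <- function(fit, profiles) {
  grid <- expand.grid(lsoa_idx = seq_len(nrow(profiles)),
                      agesex = AGESEX_LEVELS, stringsAsFactors = FALSE)
  n <- nrow(grid)
  X <- matrix(0, n, length(fit$term_names), dimnames = list(NULL, fit$term_names))
  X[, "(Intercept)"] <- 1
  for (lvl in setdiff(AGESEX_LEVELS, AGESEX_REFERENCE))
    X[, agesex_colname(lvl)] <- as.numeric(grid$agesex == lvl)
  imd <- profiles$imd_decile[grid$lsoa_idx]
  for (d in 1:9) X[, paste0("imd_", d)] <- as.numeric(imd == d)
  X[, "rural"] <- profiles$rural_flag[grid$lsoa_idx]
  list(grid = grid, X = X)
}

#' Predict poststratification-cell probabilities
#'
#' For every LSOA x age-sex cell, the posterior-predictive probability:
#' the average over posterior draws of `invlogit(b0 + x'b + u_j)` — the mean
#' of the inverse-logit, not the inverse-logit of the mean, which matters
#' under the nonlinear link.  For LSOAs without respondents, `u_j` is either
#' zero (`"posterior_mean_zero_fill"`, the default: coefficients are applied
#' with the varying effect only where the LSOA was represented) or a fresh
#' `N(0, sigma2_u)` draw per posterior draw (`"integrate_draws"`, which
#' propagates between-LSOA heterogeneity instead of shrinking unrepresented
#' areas to the regional profile).
#'
#' @param fit a `pain_fit`.
#' @param geography the study geography.
#' @param effect_policy unrepresented-LSOA policy; see above.
#' @param seed seed for the fresh draws under `"integrate_draws"`.
#' @return data.frame with lsoa_code, agesex, probability.
#' @export
predict_cell_probabilities <- function(fit, geography,
                                       effect_policy = c("posterior_mean_zero_fill",
                                                         "integrate_draws"),
                                       seed = 1L) {
  effect_policy <- match.arg(effect_policy)
  profiles <- geography$profiles
  cd <- cell_design_matrix(fit, profiles)
  S <- nrow(fit$beta_draws)
  eta_fixed <- cd$X %*% t(fit$beta_draws)  # cells x draws

  u_mat <- matrix(0, nrow(profiles), S)
  represented <- match(fit$lsoa_levels, profiles$lsoa_code)
  check_flag(!anyNA(represented), "fit contains LSOAs absent from the geography")
  u_mat[represented, ] <- t(fit$u_draws)
  if (effect_policy == "integrate_draws") {
    unrep <- setdiff(seq_len(nrow(profiles)), represented)
    if (length(unrep) > 0) {
      set.seed(derive_seed(seed, 303L))
      u_mat[unrep, ] <- rnorm(length(unrep) * S, 0,
                              sqrt(rep(fit$sigma2_draws, each = length(unrep))))
    }
  }

  prob <- rowMeans(invlogit(eta_fixed + u_mat[cd$grid$lsoa_idx, , drop = FALSE]))
  data.frame(lsoa_code = profiles$lsoa_code[cd$grid$lsoa_idx],
             agesex = cd$grid$agesex, probability = prob,
             stringsAsFactors = FALSE)
}

#' Predict a single cell probability
#'
#' Scalar convenience wrapper around [predict_cell_probabilities()].
#'
#' @param fit a `pain_fit`.
#' @param geography the study geography.
#' @param lsoa_code one LSOA code.
#' @param category one of the 12 age-sex categories.
#' @param ... passed to [predict_cell_probabilities()].
#' @return probability in (0, 1).
#' @export
predict_cell_probability <- function(fit, geography, lsoa_code, category, ...) {
  check_flag(lsoa_code %in% geography$profiles$lsoa_code, "unknown LSOA '%s'", lsoa_code)
  check_flag(category %in% AGESEX_LEVELS, "unknown age-sex category '%s'", category)
  p <- predict_cell_probabilities(fit, geography, ...)
  p$probability[p$lsoa_code == lsoa_code & p$agesex == category]
}

#' Aggregate cell probabilities to prevalence estimates
#'
#' Prevalence of a geography is the population-weighted mean of its cell
#' probabilities, `100 * sum(n_c p_c) / sum(n_c)`, with the estimated
#' affected count `sum(n_c p_c)` carried alongside.  Aggregates are
#' consistent by construction: the region's estimated count equals the sum
#' of LA counts equals the sum over all cells.
#'
#' @param cell_probs data.frame from [predict_cell_probabilities()] (or any
#'   lsoa_code/agesex/probability table covering every populated cell).
#' @param geography the study geography (population cells and lineage).
#' @param level `"lsoa"`, `"msoa"`, `"la"` or `"region"`.
#' @param outcome label recorded in the output.
#' @return data.frame: geography_id, level, outcome, prevalence_percent,
#'   estimated_count, population.
#' @export
aggregate_prevalence <- function(cell_probs, geography,
                                 level = c("lsoa", "msoa", "la", "region"),
                                 outcome = "chronic_pain") {
  level <- match.arg(level)
  pop <- merge(geography$population, geography$profiles, by = "lsoa_code", sort = FALSE)
  pop$agesex <- paste(pop$sex, pop$age_group, sep = "_")
  m <- merge(pop, cell_probs, by = c("lsoa_code", "agesex"), all.x = TRUE, sort = FALSE)
  if (anyNA(m$probability)) {
    bad <- m[is.na(m$probability), c("lsoa_code", "agesex")][1, ]
    stop_painscape("no probability for populated cell %s / %s", bad$lsoa_code, bad$agesex)
  }
  id <- switch(level, lsoa = m$lsoa_code, msoa = m$msoa_code,
               la = m$la_name, region = rep("region", nrow(m)))
  num <- tapply(m$probability * m$count, id, sum)
  den <- tapply(m$count, id, sum)
  if (any(den == 0))
    stop_painscape("geography with zero population: %s", names(den)[den == 0][1])
  out <- data.frame(geography_id = names(den), level = level, outcome = outcome,
                    prevalence_percent = 100 * as.numeric(num) / as.numeric(den),
                    estimated_count = as.numeric(num),
                    population = as.numeric(den),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply ethnicity correction to LSOA estimates
#'
#' Multiplies each LSOA's prevalence by its proportion-weighted blend of the
#' group factors, `sum_g(proportion_g * factor_g)` — equivalent to assuming
#' each group's prevalence is the White prevalence times its factor.
#' Corrected prevalence is truncated at 100% (with a warning) since a
#' multiplicative correction is unbounded in principle.
#'
#' @param estimates LSOA-level output of [aggregate_prevalence()].
#' @param geography the study geography (supplies ethnicity proportions,
#'   which must sum to 1 within 1e-6 per LSOA).
#' @param factors a [correction_factors()] matrix.
#' @param outcome which factor column to use; defaults to the estimates'
#'   outcome.
#' @return the estimates with prevalence_percent and estimated_count
#'   corrected, a `corrected` flag set and the effective `multiplier`
#'   recorded.
#' @export
apply_ethnicity_correction <- function(estimates, geography,
                                       factors = correction_factors(),
                                       outcome = NULL) {
  outcome <- outcome %||% estimates$outcome[1]
  check_flag(outcome %in% colnames(factors), "no correction factors for outcome '%s'", outcome)
  check_flag(all(estimates$level == "lsoa"),
             "correction is applied at LSOA level (then re-aggregated)")
  check_flag(is.null(estimates$corrected) || !any(estimates$corrected),
             "estimates are already corrected")
  eth <- geography$ethnicity
  props <- as.matrix(eth[, ETHNIC_GROUPS])
  check_flag(all(props >= 0), "negative ethnicity proportion")
  check_flag(all(abs(rowSums(props) - 1) < 1e-6),
             "ethnicity proportions must sum to 1 within 1e-6")
  mult <- setNames(as.numeric(props %*% factors[ETHNIC_GROUPS, outcome]),
                   eth$lsoa_code)
  i <- match(estimates$geography_id, names(mult))
  check_flag(!anyNA(i), "estimate for LSOA with no ethnicity profile")
  corrected <- estimates$prevalence_percent * mult[i]
  if (any(corrected > 100)) {
    warning(sprintf("%d corrected prevalence(s) truncated at 100%%",
                    sum(corrected > 100)), call. = FALSE)
    corrected <- pmin(corrected, 100)
  }
  out <- estimates
  out$prevalence_percent <- unname(corrected)
  out$estimated_count <- out$prevalence_percent / 100 * out$population
  out$corrected <- TRUE
  out$multiplier <- unname(mult[i])
  out
}

#' Subgroup prevalence (age-sex, IMD decile, rurality)
#'
#' Population-weighted prevalence across the region per level of a
#' demographic or area grouping, in canonical group order.  Groups with no
#' population are omitted with a warning.
#'
#' @param cell_probs cell probabilities ([predict_cell_probabilities()]).
#' @param geography the study geography.
#' @param grouping `"agesex"`, `"imd_decile"` or `"rurality"`.
#' @param outcome label recorded in the output.
#' @return data.frame: group, outcome, prevalence_percent, population.
#' @export
subgroup_prevalence <- function(cell_probs, geography,
                                grouping = c("agesex", "imd_decile", "rurality"),
                                outcome = "chronic_pain") {
  grouping <- match.arg(grouping)
  pop <- merge(geography$population, geography$profiles, by = "lsoa_code", sort = FALSE)
  pop$agesex <- paste(pop$sex, pop$age_group, sep = "_")
  m <- merge(pop, cell_probs, by = c("lsoa_code", "agesex"), all.x = TRUE, sort = FALSE)
  check_flag(!anyNA(m$probability), "cell probabilities must cover every populated cell")
  g <- switch(grouping,
              agesex = factor(m$agesex, levels = AGESEX_LEVELS),
              imd_decile = factor(m$imd_decile, levels = 1:10),
              rurality = factor(ifelse(m$rural_flag == 1, "rural", "urban"),
                                levels = c("urban", "rural")))
  num <- tapply(m$probability * m$count, g, sum)
  den <- tapply(m$count, g, sum)
  empty <- is.na(den) | den == 0
  if (any(empty))
    warning(sprintf("empty group(s) omitted: %s",
                    paste(levels(g)[empty], collapse = ", ")), call. = FALSE)
  data.frame(group = levels(g)[!empty], outcome = outcome,
             prevalence_percent = 100 * as.numeric(num[!empty]) / as.numeric(den[!empty]),
             population = as.numeric(den[!empty]),
             stringsAsFactors = FALSE, row.names = NULL)
}
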