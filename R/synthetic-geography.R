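#' Specification of a synthetic study region
#'
#' Describes the geography the synthetic-data generator emulates: LSOAs
#' (lower layer super output areas, the ~1,500-resident neighbourhood unit)
#' nested in MSOAs nested in local authorities, with an age-sex population
#' structure for residents aged 35 and over, an IMD (index of multiple
#' deprivation) decile profile, a rural/urban mix and ethnicity proportions.
#'
#' Defaults emulate the North Staffordshire study region: 298 LSOAs split
#' 159/80/59 across Stoke-on-Trent, Newcastle-under-Lyme and Staffordshire
#' Moorlands with 35+ populations of 136,718 / 74,399 / 64,274; a heavily
#' deprived, almost entirely urban Stoke (about 30% of its neighbourhoods in
#' the most deprived decile) against more affluent, partly rural neighbours
#' (around 10 of the 298 LSOAs in the most affluent decile, mostly outside
#' Stoke); and a population about 91% White.
#'
#' @param n_lsoas total number of LSOAs.
#' @param local_authorities data.frame with columns `name`, `n_lsoas`,
#'   `n_msoas`, `population_35plus`.
#' @param imd_decile_distribution matrix (one row per local authority, 10
#'   columns) of probabilities over IMD deciles 1 (most deprived) to 10
#'   (most affluent); rows must sum to 1.
#' @param rural_fraction per-LA probability that an LSOA is rural.
#' @param age_structure proportions of the 35+ population in the six age
#'   groups 35-44, ..., 85+; must sum to 1.
#' @param female_share proportion female within each age group.
#' @param ethnicity list with Dirichlet mean vectors `typical_mean` and
#'   `diverse_mean` over the five ethnic groups (White, Asian excluding
#'   Chinese, Black, Chinese, Mixed/multiple), a concentration parameter
#'   `concentration`, and per-LA probabilities `diverse_prob` that an LSOA
#'   draws from the diverse profile.
#' @return an object of class `geography_spec`.
#' @export
geography_spec <- function(n_lsoas = 298L,
                           local_authorities = data.frame(
                             name = c("Stoke-on-Trent", "Newcastle-under-Lyme",
                                      "Staffordshire Moorlands"),
                             n_lsoas = c(159L, 80L, 59L),
                             n_msoas = c(34L, 16L, 13L),
                             population_35plus = c(136718, 74399, 64274)
                           ),
                           imd_decile_distribution = rbind(
                             c(0.30, 0.20, 0.14, 0.10, 0.08, 0.06, 0.05, 0.04, 0.02, 0.01),
                             c(0.08, 0.10, 0.11, 0.12, 0.12, 0.12, 0.11, 0.10, 0.08, 0.06),
                             c(0.02, 0.05, 0.08, 0.12, 0.15, 0.16, 0.15, 0.13, 0.09, 0.05)
                           ),
                           rural_fraction = c(0.01, 0.35, 0.70),
                           age_structure = c(0.24, 0.21, 0.20, 0.17, 0.12, 0.06),
                           female_share = c(0.50, 0.50, 0.51, 0.52, 0.57, 0.65),
                           ethnicity = list(
                             typical_mean = c(0.945, 0.025, 0.010, 0.007, 0.013),
                             diverse_mean = c(0.700, 0.220, 0.040, 0.015, 0.025),
                             concentration = 400,
                             diverse_prob = c(0.22, 0.04, 0.01)
                           )) {
  spec <- structure(
    list(n_lsoas = as.integer(n_lsoas),
         local_authorities = local_authorities,
         imd_decile_distribution = imd_decile_distribution,
         rural_fraction = rural_fraction,
         age_structure = age_structure,
         female_share = female_share,
         ethnicity = ethnicity),
    class = "geography_spec")
  validate_geography_spec(spec)
  spec
}

validate_geography_spec <- function(spec) {
  la <- spec$local_authorities
  check_flag(is.data.frame(la) && nrow(la) >= 1, "local_authorities must be a non-empty data.frame")
  check_flag(all(c("name", "n_lsoas", "n_msoas", "population_35plus") %in% names(la)),
             "local_authorities must have columns name, n_lsoas, n_msoas, population_35plus")
  check_flag(sum(la$n_lsoas) == spec$n_lsoas,
             "per-LA LSOA counts (%d) must sum to n_lsoas (%d)", sum(la$n_lsoas), spec$n_lsoas)
  check_flag(all(la$population_35plus > 0), "populations must be positive")
  check_flag(all(la$n_msoas >= 1 & la$n_msoas <= la$n_lsoas), "n_msoas must be in [1, n_lsoas] per LA")
  check_flag(nrow(spec$imd_decile_distribution) == nrow(la) &&
               ncol(spec$imd_decile_distribution) == 10,
             "imd_decile_distribution must be one row of 10 decile probabilities per LA")
  check_flag(all(abs(rowSums(spec$imd_decile_distribution) - 1) < 1e-9),
             "imd_decile_distribution rows must sum to 1")
  check_flag(length(spec$rural_fraction) == nrow(la) &&
               all(spec$rural_fraction >= 0 & spec$rural_fraction <= 1),
             "rural_fraction must be one probability per LA")
  check_flag(length(spec$age_structure) == 6 && abs(sum(spec$age_structure) - 1) < 1e-9,
             "age_structure must be 6 proportions summing to 1")
  check_flag(length(spec$female_share) == 6 && all(spec$female_share > 0 & spec$female_share < 1),
             "female_share must be 6 proportions in (0,1)")
  eth <- spec$ethnicity
  check_flag(length(eth$typical_mean) == 5 && length(eth$diverse_mean) == 5 &&
               abs(sum(eth$typical_mean) - 1) < 1e-9 && abs(sum(eth$diverse_mean) - 1) < 1e-9,
             "ethnicity mean vectors must be 5 proportions summing to 1")
  check_flag(length(eth$diverse_prob) == nrow(la), "ethnicity$diverse_prob must be one value per LA")
  invisible(spec)
}

# largest-remainder apportionment of an integer total over weights;
# deterministic tie-break by position
apportion <- function(total, weights) {
  check_flag(total >= 0 && all(weights >= 0) && sum(weights) > 0, "invalid apportionment inputs")
  raw <- total * weights / sum(weights)
  out <- floor(raw)
  rem <- round(total - sum(out))
  if (rem > 0) {
    idx <- order(-(raw - out), seq_along(raw))[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  as.integer(out)
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Generate a synthetic study geography
#'
#' Draws a full region: LSOA profiles (administrative lineage, IMD decile,
#' rural flag), age-sex population cells, and 5-group ethnicity proportions.
#' LA population totals are apportioned exactly (largest-remainder rounding)
#' over LSOAs and, within an LSOA, over its 12 age-sex cells, so counts are
#' conserved at every level.
#'
#' @param spec a [geography_spec()].
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return an object of class `pain_geography`: a list of data.frames
#'   `profiles` (lsoa_code, msoa_code, la_name, imd_decile, rural_flag),
#'   `population` (lsoa_code, sex, age_group, count) and `ethnicity`
#'   (lsoa_code plus one proportion column per ethnic group).
#' @export
generate_geography <- function(spec = geography_spec(), seed = 1L) {
  validate_geography_spec(spec)
  set.seed(derive_seed(seed, 101L))
  la <- spec$local_authorities

  profiles <- vector("list", nrow(la))
  population <- vector("list", nrow(la))
  ethnicity <- vector("list", nrow(la))
  lsoa_offset <- 0L
  msoa_offset <- 0L

  for (k in seq_len(nrow(la))) {
    nl <- la$n_lsoas[k]
    codes <- sprintf("SYN%05d", lsoa_offset + seq_len(nl))
    msoa_of <- sort(rep_len(seq_len(la$n_msoas[k]), nl))
    msoa_codes <- sprintf("SYNM%03d", msoa_offset + msoa_of)
    imd <- sample(1:10, nl, replace = TRUE, prob = spec$imd_decile_distribution[k, ])
    rural <- as.integer(runif(nl) < spec$rural_fraction[k])
    profiles[[k]] <- data.frame(lsoa_code = codes, msoa_code = msoa_codes,
                                la_name = la$name[k], imd_decile = imd,
                                rural_flag = rural, stringsAsFactors = FALSE)

    # LSOA 35+ population sizes: mildly unequal (gamma weights), LA total exact
    lsoa_pop <- apportion(la$population_35plus[k], rgamma(nl, shape = 50, rate = 1))
    cell_weights <- as.vector(t(cbind(
      spec$age_structure * (1 - spec$female_share),
      spec$age_structure * spec$female_share
    )))  # order: M then F within each age group, matching AGESEX_LEVELS
    cells <- t(vapply(lsoa_pop, apportion, integer(12), weights = cell_weights))
    population[[k]] <- data.frame(
      lsoa_code = rep(codes, each = 12),
      sex = rep(rep(SEXES, times = 6), nl),
      age_group = rep(rep(AGE_GROUPS, each = 2), nl),
      count = as.integer(t(cells)), stringsAsFactors = FALSE)

    eth <- spec$ethnicity
    diverse <- runif(nl) < eth$diverse_prob[k]
    props <- t(vapply(seq_len(nl), function(i) {
      mean_vec <- if (diverse[i]) eth$diverse_mean else eth$typical_mean
      rdirichlet1(mean_vec * eth$concentration)
    }, numeric(5)))
    colnames(props) <- ETHNIC_GROUPS
    ethnicity[[k]] <- data.frame(lsoa_code = codes, props, stringsAsFactors = FALSE)

    lsoa_offset <- lsoa_offset + nl
    msoa_offset <- msoa_offset + la$n_msoas[k]
  }

  structure(list(profiles = do.call(rbind, profiles),
                 population = do.call(rbind, population),
                 ethnicity = do.call(rbind, ethnicity),
                 spec = spec),
            class = "pain_geography")
}

#' @export
print.pain_geography <- function(x, ...) {
  cat(sprintf("Synthetic study geography: %d LSOAs in %d local authorities\n",
              nrow(x$profiles), length(unique(x$profiles$la_name))))
  cat(sprintf("  35+ population: %s persons in %d age-sex cells\n",
              format(sum(x$population$count), big.mark = ","), nrow(x$population)))
  invisible(x)
}
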