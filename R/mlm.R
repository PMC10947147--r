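#' Model specification for the two-level logistic regression
#'
#' Defines the model `logit P(Y=1) = b0 + x'b + u_j` with fixed effects for
#' the 11 non-reference age-sex categories (reference men 35-44), IMD
#' deciles 1-9 (reference decile 10), a rural indicator (reference urban)
#' and optionally mean-centred depression and/or BMI, plus an LSOA random
#' intercept `u_j ~ N(0, sigma2_u)`.
#'
#' Priors are weakly informative: Normal(0, `beta_sd`^2) on all fixed
#' effects and, by default, half-Cauchy(0, `sigma_scale`) on `sigma_u`
#' (configurable to inverse-gamma on `sigma2_u`).  Desk-scale MCMC defaults
#' (2 chains, 2,000 burn-in, 5,000 stored draws) are deliberately far below
#' production-scale runs of several hundred thousand iterations; the
#' Polya-Gamma Gibbs sampler mixes well enough that these suffice for the
#' synthetic region, and all settings are overridable.
#'
#' @param outcome `"chronic_pain"` or `"high_impact"`.
#' @param covariates optional subset of `c("depression", "bmi")` to include
#'   as centred continuous terms.
#' @param prior list: `beta_sd`, `sigma_prior` (`"half_cauchy"` or
#'   `"inv_gamma"`), `sigma_scale`, `ig_shape`, `ig_rate`.
#' @param mcmc list: `chains`, `burn`, `iter` (stored iterations per chain),
#'   `thin`, `seed`.
#' @param min_ess,max_rhat convergence gate applied to all reported
#'   parameters; violations are flagged in the fit's diagnostics (with a
#'   warning), never silently ignored.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("chronic_pain", "high_impact"),
                       covariates = character(),
                       prior = list(),
                       mcmc = list(),
                       min_ess = 400, max_rhat = 1.05) {
  outcome <- match.arg(outcome)
  check_flag(all(covariates %in% c("depression", "bmi")),
             "covariates must be a subset of c('depression', 'bmi')")
  prior <- modifyList(list(beta_sd = 10, sigma_prior = "half_cauchy",
                           sigma_scale = 5, ig_shape = 0.001, ig_rate = 0.001),
                      prior)
  check_flag(prior$sigma_prior %in% c("half_cauchy", "inv_gamma"),
             "sigma_prior must be 'half_cauchy' or 'inv_gamma'")
  mcmc <- modifyList(list(chains = 2L, burn = 2000L, iter = 5000L,
                          thin = 1L, seed = 1L), mcmc)
  check_flag(all(unlist(mcmc[c("chains", "burn", "iter", "thin")]) > 0),
             "mcmc settings must be positive")
  structure(list(outcome = outcome, covariates = covariates, prior = prior,
                 mcmc = mcmc, min_ess = min_ess, max_rhat = max_rhat),
            class = "model_spec")
}

#' Build the model design from analysis records
#'
#' Produces the outcome vector, dummy-coded fixed-effect matrix (treatment
#' coding against the stated reference categories), centred continuous
#' columns and the LSOA index.  Column order is fixed and recorded: age-sex
#' contrasts (age ascending, men before women), IMD deciles 1..9, rural,
#' then continuous terms.  Centring constants are computed here from the
#' supplied records and travel with the design and fit, so predictions are
#' reproducible.
#'
#' @param records complete-case analysis records.
#' @param geography the study geography (supplies IMD decile and rurality
#'   per LSOA); every record's LSOA must appear in it.
#' @param spec a [model_spec()].
#' @return an object of class `pain_design`.
#' @export
build_design <- function(records, geography, spec = model_spec()) {
  profiles <- geography$profiles
  unknown <- setdiff(unique(records$lsoa_code), profiles$lsoa_code)
  if (length(unknown) > 0)
    stop_painscape("record(s) reference unknown LSOA(s): %s",
                   paste(utils::head(unknown, 5), collapse = ", "))
  y <- as.integer(records[[spec$outcome]])
  check_flag(!anyNA(y), "outcome '%s' has missing values; apply filter_complete_cases first",
             spec$outcome)

  prof_idx <- match(records$lsoa_code, profiles$lsoa_code)
  imd <- profiles$imd_decile[prof_idx]
  rural <- profiles$rural_flag[prof_idx]
  agesex <- factor(records$agesex, levels = AGESEX_LEVELS)

  cols <- list("(Intercept)" = rep(1, nrow(records)))
  for (lvl in setdiff(AGESEX_LEVELS, AGESEX_REFERENCE))
    cols[[agesex_colname(lvl)]] <- as.numeric(agesex == lvl)
  for (d in 1:9)
    cols[[paste0("imd_", d)]] <- as.numeric(imd == d)
  cols[["rural"]] <- as.numeric(rural)
  X <- do.call(cbind, cols)

  centring <- numeric(0)
  if ("depression" %in% spec$covariates) {
    check_flag(!anyNA(records$depression_score),
               "depression_score has missing values; filter to the sensitivity sample first")
    centring["depression"] <- mean(records$depression_score)
    X <- cbind(X, depression_c = records$depression_score - centring[["depression"]])
  }
  if ("bmi" %in% spec$covariates) {
    check_flag(!anyNA(records$bmi),
               "bmi has missing values; filter to the sensitivity sample first")
    centring["bmi"] <- mean(records$bmi)
    X <- cbind(X, bmi_c = records$bmi - centring[["bmi"]])
  }

  empty <- colnames(X)[-1][colSums(X[, -1, drop = FALSE] != 0) == 0]
  if (length(empty) > 0)
    warning(sprintf("fixed-effect column(s) with no respondents (retained): %s",
                    paste(empty, collapse = ", ")), call. = FALSE)

  lsoa_levels <- sort(unique(records$lsoa_code))
  structure(list(y = y, X = X,
                 group = match(records$lsoa_code, lsoa_levels),
                 lsoa_levels = lsoa_levels,
                 centring = centring, outcome = spec$outcome, spec = spec),
            class = "pain_design")
}

new_pain_fit <- function(method, design, beta_draws, u_draws, sigma2_draws,
                         diagnostics = NULL) {
  qs <- function(m) t(apply(m, 2, function(v)
    c(mean = mean(v), sd = sd(v), q2.5 = unname(quantile(v, 0.025, type = 7)),
      q97.5 = unname(quantile(v, 0.975, type = 7)))))
  coef_tab <- as.data.frame(qs(cbind(beta_draws, sigma2_u = as.numeric(sigma2_draws))))
  coef_tab <- cbind(parameter = rownames(coef_tab), coef_tab)
  rownames(coef_tab) <- NULL
  structure(list(method = method,
                 coefficients = coef_tab,
                 beta_draws = beta_draws,
                 u_draws = u_draws,
                 sigma2_draws = sigma2_draws,
                 lsoa_levels = design$lsoa_levels,
                 term_names = colnames(design$X),
                 centring = design$centring,
                 outcome = design$outcome,
                 diagnostics = diagnostics),
            class = "pain_fit")
}

# split-chain potential scale reduction (each chain halved, pooled PSRF)
split_rhat <- function(draws_by_chain) {
  halves <- do.call(c, lapply(draws_by_chain, function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[h + seq_len(h)])
  }))
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  B <- n * var(means)
  W <- mean(vars)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the multilevel logistic model by MCMC
#'
#' Gibbs sampler with Polya-Gamma data augmentation: the logistic likelihood
#' is augmented with one PG(1, psi_i) latent per observation, making the
#' fixed effects and random intercepts conditionally Gaussian, so all
#' updates are exact conditional draws (no tuning).  Chains are seeded
#' deterministically from the spec's seed.  Diagnostics (split-chain
#' potential scale reduction and effective sample size, via `coda`) are
#' computed for every fixed effect and `sigma2_u`; failures of the
#' convergence gate are flagged with a warning and recorded in the fit.
#'
#' @param design a [build_design()] result with at least 2 represented
#'   LSOAs.
#' @param spec optional [model_spec()] overriding the one in the design.
#' @param sigma2_fixed optionally fix the between-LSOA variance at a value
#'   (0 pins all random intercepts at zero, giving a plain Bayesian logistic
#'   regression); `NULL` (default) samples it.
#' @return an object of class `pain_fit` with posterior draws (`beta_draws`,
#'   `u_draws`, `sigma2_draws`), a coefficient summary table, the centring
#'   constants and diagnostics.
#' @export
fit_mcmc <- function(design, spec = NULL, sigma2_fixed = NULL) {
  spec <- spec %||% design$spec
  J <- length(design$lsoa_levels)
  check_flag(J >= 2 || !is.null(sigma2_fixed),
             "between-LSOA variance is unidentifiable with a single LSOA")
  check_separation(design)

  mc <- spec$mcmc
  sigma_prior <- if (!is.null(sigma2_fixed)) 2L
                 else if (spec$prior$sigma_prior == "half_cauchy") 0L else 1L
  chains <- lapply(seq_len(mc$chains), function(ch) {
    set.seed(derive_seed(mc$seed, 7000L + ch))
    .gibbs_logit_mixed(design$y, design$X, design$group - 1L, J,
                       as.integer(mc$burn), as.integer(mc$iter),
                       as.integer(mc$thin),
                       spec$prior$beta_sd^2, sigma_prior,
                       spec$prior$sigma_scale,
                       spec$prior$ig_shape, spec$prior$ig_rate,
                       sigma2_fixed %||% -1)
  })

  beta_draws <- do.call(rbind, lapply(chains, `[[`, "beta"))
  colnames(beta_draws) <- colnames(design$X)
  u_draws <- do.call(rbind, lapply(chains, `[[`, "u"))
  colnames(u_draws) <- design$lsoa_levels
  sigma2_draws <- do.call(c, lapply(chains, `[[`, "sigma2"))

  monitored <- c(colnames(design$X), if (is.null(sigma2_fixed)) "sigma2_u")
  diag_tab <- data.frame(parameter = monitored, ess = NA_real_, rhat = NA_real_)
  for (i in seq_along(monitored)) {
    per_chain <- lapply(seq_len(mc$chains), function(ch)
      if (monitored[i] == "sigma2_u") chains[[ch]]$sigma2
      else chains[[ch]]$beta[, i])
    diag_tab$ess[i] <- sum(vapply(per_chain, function(v)
      unname(coda::effectiveSize(coda::mcmc(v))), 0))
    diag_tab$rhat[i] <- split_rhat(per_chain)
  }
  converged <- all(diag_tab$ess >= spec$min_ess) && all(diag_tab$rhat <= spec$max_rhat)
  if (!converged)
    warning(sprintf(
      "convergence gate not met (min ESS %.0f < %g and/or max Rhat %.3f > %g); inspect $diagnostics",
      min(diag_tab$ess), spec$min_ess, max(diag_tab$rhat), spec$max_rhat), call. = FALSE)

  fit <- new_pain_fit("mcmc", design, beta_draws, u_draws, sigma2_draws,
                      diagnostics = list(table = diag_tab, converged = converged,
                                         settings = mc))
  fit
}

check_separation <- function(design) {
  dummy_cols <- which(apply(design$X[, -1, drop = FALSE], 2,
                            function(v) all(v %in% c(0, 1)))) + 1L
  for (k in dummy_cols) {
    yk <- design$y[design$X[, k] == 1]
    if (length(yk) > 0 && length(unique(yk)) == 1)
      warning(sprintf(
        "separation: all outcomes identical in category '%s'; the prior regularises this coefficient",
        colnames(design$X)[k]), call. = FALSE)
  }
  invisible(NULL)
}

#' Fast approximate fit (penalised likelihood)
#'
#' Point estimation of the same model by Laplace-type penalised likelihood
#' via [lme4::glmer()] (`nAGQ = 0`).  Returns the same `pain_fit` shape as
#' [fit_mcmc()] with degenerate one-draw "posteriors", so the
#' poststratification and bootstrap code is agnostic to the fitter.  This is
#' an approximation: no posterior uncertainty, and variance estimates are
#' mode-based.  Deterministic given the data.
#'
#' @inheritParams fit_mcmc
#' @return a `pain_fit` with `method = "approximate"`.
#' @export
fit_approximate <- function(design, spec = NULL) {
  spec <- spec %||% design$spec
  J <- length(design$lsoa_levels)
  check_flag(J >= 2, "between-LSOA variance is unidentifiable with a single LSOA")

  d <- as.data.frame(design$X[, -1, drop = FALSE])
  d$.y <- design$y
  d$.g <- factor(design$group, levels = seq_len(J))
  form <- stats::reformulate(c(colnames(design$X)[-1], "(1 | .g)"), ".y")
  fit <- tryCatch(
    suppressMessages(lme4::glmer(
      form, data = d, family = binomial(),
      nAGQ = 0L,
      control = lme4::glmerControl(calc.derivs = FALSE,
                                   check.conv.singular = "ignore"))),
    error = function(e) stop_painscape("approximate fit failed to converge: %s",
                                       conditionMessage(e)))

  est <- lme4::fixef(fit)
  names(est)[1] <- "(Intercept)"
  # columns dropped as rank-deficient (e.g. categories with no respondents)
  # take coefficient 0 — the value is immaterial for the fitted data and
  # matches the prior centre used by the MCMC fitter for such categories
  beta <- setNames(rep(0, ncol(design$X)), colnames(design$X))
  dropped <- setdiff(names(beta), names(est))
  if (length(dropped) > 0)
    warning(sprintf("coefficient(s) unidentifiable and set to 0: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  beta[names(est)] <- est
  u <- setNames(rep(0, J), design$lsoa_levels)
  re <- lme4::ranef(fit)$.g
  u[as.integer(rownames(re))] <- re[, 1]
  sigma2 <- unname(lme4::VarCorr(fit)$.g[1, 1])

  new_pain_fit("approximate", design,
               matrix(beta, nrow = 1, dimnames = list(NULL, colnames(design$X))),
               matrix(u, nrow = 1, dimnames = list(NULL, design$lsoa_levels)),
               sigma2)
}

#' Variance partition coefficient for the logistic multilevel model
#'
#' Share of residual latent-propensity variance attributable to the LSOA
#' level, under the latent-threshold formulation in which the individual
#' level contributes the standard-logistic variance pi^2/3:
#' `sigma2_u / (sigma2_u + pi^2/3)`.  Monotone increasing in `sigma2_u` and
#' bounded in `[0, 1)`.
#'
#' @param sigma2_u between-LSOA variance(s), >= 0.
#' @return proportion(s) in `[0, 1)`.
#' @export
compute_vpc <- function(sigma2_u) {
  check_flag(all(sigma2_u >= 0), "sigma2_u must be non-negative")
  sigma2_u / (sigma2_u + pi^2 / 3)
}

#' @export
print.pain_fit <- function(x, ...) {
  cat(sprintf("Two-level logistic fit (%s), outcome: %s\n", x$method, x$outcome))
  cat(sprintf("  %d fixed effects, %d represented LSOAs, %d draw(s)\n",
              ncol(x$beta_draws), length(x$lsoa_levels), nrow(x$beta_draws)))
  cat(sprintf("  sigma2_u: %.4f (VPC %.2f%%)\n",
              mean(x$sigma2_draws), 100 * compute_vpc(mean(x$sigma2_draws))))
  if (!is.null(x$diagnostics))
    cat(sprintf("  convergence gate: %s\n",
                if (x$diagnostics$converged) "met" else "NOT met"))
  invisible(x)
}

#' @export
coef.pain_fit <- function(object, ...) {
  setNames(colMeans(object$beta_draws), object$term_names)
}
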