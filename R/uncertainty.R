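#' Percentile interval from bootstrap samples
#'
#' Empirical `(1-level)/2` and `1-(1-level)/2` quantiles under the
#' linear-interpolation quantile definition (type 7, the common scientific
#' default), fixed here for reproducibility.
#'
#' @param samples numeric vector of at least 2 finite values.
#' @param level interval level in (0, 1).
#' @return named numeric `c(lower, upper)`.
#' @export
percentile_interval <- function(samples, level = 0.95) {
  samples <- samples[is.finite(samples)]
  check_flag(length(samples) >= 2, "need at least 2 finite samples")
  check_flag(is.numeric(level) && length(level) == 1 && level > 0 && level < 1,
             "level must be a single value strictly inside (0, 1)")
  alpha <- (1 - level) / 2
  q <- quantile(samples, c(alpha, 1 - alpha), type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Bootstrap settings
#'
#' @param n_replicates number of bootstrap replicates (production-scale
#'   analyses use thousands; the desk default is 200).
#' @param resampling_unit `"respondents_within_lsoa"` (default: respondents
#'   resampled with replacement within their LSOA, preserving per-LSOA
#'   sample sizes so the random-effect structure is comparable across
#'   replicates) or `"respondents_pooled"`.
#' @param fitter fitter used inside the loop: `"approximate"` (default;
#'   production MCMC inside a bootstrap is typically not desk-feasible) or
#'   `"mcmc"`.
#' @param ci_level confidence level; `n_replicates` must be at least
#'   `2 / (1 - ci_level)` for the percentile method to be defined.
#' @param seed integer; replicate seeds are derived deterministically from
#'   it, so fixed seed gives bit-identical intervals.
#' @return an object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_replicates = 200L,
                           resampling_unit = c("respondents_within_lsoa",
                                               "respondents_pooled"),
                           fitter = c("approximate", "mcmc"),
                           ci_level = 0.95, seed = 1L) {
  resampling_unit <- match.arg(resampling_unit)
  fitter <- match.arg(fitter)
  check_flag(ci_level > 0 && ci_level < 1, "ci_level must be in (0, 1)")
  check_flag(n_replicates >= 2 / (1 - ci_level),
             "n_replicates (%d) must be >= 2/(1 - ci_level) = %.0f",
             n_replicates, 2 / (1 - ci_level))
  structure(list(n_replicates = as.integer(n_replicates),
                 resampling_unit = resampling_unit, fitter = fitter,
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "bootstrap_spec")
}

# one full estimate pass: design -> fit -> cells -> corrected LSOA prevalences
boot_one_pass <- function(records, geography, mspec, fitter, factors, correct) {
  design <- build_design(records, geography, mspec)
  fit <- if (fitter == "mcmc") fit_mcmc(design) else fit_approximate(design)
  cells <- predict_cell_probabilities(fit, geography)
  est <- aggregate_prevalence(cells, geography, "lsoa", mspec$outcome)
  if (correct) est <- apply_ethnicity_correction(est, geography, factors)
  setNames(est$prevalence_percent, est$geography_id)
}

#' Bootstrap percentile confidence intervals for LSOA estimates
#'
#' Re-runs the whole estimation chain (model fit, poststratification,
#' ethnicity correction) on each resampled dataset and forms per-LSOA
#' percentile intervals over the replicate estimates.  The point estimate
#' comes from the original, non-resampled fit.  A replicate in which an LSOA
#' loses all its respondents is retained — that LSOA simply falls back to
#' the unrepresented-LSOA policy for that replicate.  Replicates whose fit
#' fails are logged and skipped; more than 10% failures aborts the run,
#' since silently dropping many replicates would bias the intervals.
#'
#' @param records complete-case analysis records.
#' @param geography the study geography.
#' @param mspec a [model_spec()] for the bootstrapped outcome.
#' @param boot a [bootstrap_spec()].
#' @param factors ethnicity [correction_factors()].
#' @param correct apply the ethnicity correction inside each replicate.
#' @param progress_every emit a progress message every this many replicates
#'   (0 = silent).
#' @return data.frame: lsoa_code, outcome, point, ci_lower, ci_upper,
#'   n_effective_replicates; failed replicate count in
#'   `attr(, "n_failed")`.
#' @export
bootstrap_estimates <- function(records, geography, mspec = model_spec(),
                                boot = bootstrap_spec(),
                                factors = correction_factors(),
                                correct = TRUE, progress_every = 0L) {
  point <- boot_one_pass(records, geography, mspec, boot$fitter, factors, correct)

  by_lsoa <- split(seq_len(nrow(records)), records$lsoa_code)
  reps <- matrix(NA_real_, boot$n_replicates, length(point),
                 dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (r in seq_len(boot$n_replicates)) {
    set.seed(derive_seed(boot$seed, 5000L + r))
    idx <- if (boot$resampling_unit == "respondents_within_lsoa") {
      unlist(lapply(by_lsoa, function(ii) ii[sample.int(length(ii), replace = TRUE)]),
             use.names = FALSE)
    } else {
      sample.int(nrow(records), replace = TRUE)
    }
    est_r <- tryCatch(
      boot_one_pass(records[idx, , drop = FALSE], geography, mspec,
                    boot$fitter, factors, correct),
      error = function(e) {
        message(sprintf("bootstrap replicate %d failed: %s", r, conditionMessage(e)))
        NULL
      })
    if (is.null(est_r)) n_failed <- n_failed + 1L else reps[r, names(est_r)] <- est_r
    if (progress_every > 0 && r %% progress_every == 0)
      message(sprintf("bootstrap: %d/%d replicates", r, boot$n_replicates))
  }
  if (n_failed > 0.1 * boot$n_replicates)
    stop_painscape("%d of %d bootstrap replicates failed (> 10%%)",
                   n_failed, boot$n_replicates)

  ci <- apply(reps, 2, function(v) percentile_interval(v, boot$ci_level))
  out <- data.frame(lsoa_code = names(point), outcome = mspec$outcome,
                    point = unname(point),
                    ci_lower = unname(ci["lower", names(point)]),
                    ci_upper = unname(ci["upper", names(point)]),
                    n_effective_replicates = colSums(!is.na(reps))[names(point)],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_failed") <- n_failed
  out
}
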