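#' Pipeline configuration
#'
#' Bundles every stage's settings: the synthetic geography and ground truth
#' (simulation only), sampling chain, model specifications per outcome,
#' fitter choice, bootstrap settings, ethnicity correction factors and the
#' single master seed from which all stage seeds are derived.
#'
#' @param output_dir directory for all stage CSVs.
#' @param seed master integer seed.
#' @param geography a [geography_spec()].
#' @param truth a [true_parameters()] object.
#' @param sampling list: `sampling_fraction`, `frame_coverage`,
#'   `response_rate` (see [generate_respondents()]).
#' @param fitter `"approximate"` or `"mcmc"` for the main fit stage.
#' @param models named list of [model_spec()]s, one per outcome.
#' @param bootstrap a [bootstrap_spec()].
#' @param bootstrap_outcome outcome to bootstrap (the rarer outcome by
#'   default; production-scale interval estimation for both outcomes is a
#'   cost decision, not a methods one).
#' @param correction a [correction_factors()] matrix.
#' @param verbosity 0 = silent, 1 = stage log lines.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("painscape_"),
                            seed = 1L,
                            geography = geography_spec(),
                            truth = true_parameters(),
                            sampling = list(sampling_fraction = 0.21,
                                            frame_coverage = 0.146,
                                            response_rate = 0.519),
                            fitter = c("approximate", "mcmc"),
                            models = NULL,
                            bootstrap = bootstrap_spec(),
                            bootstrap_outcome = "high_impact",
                            correction = correction_factors(),
                            verbosity = 1L) {
  fitter <- match.arg(fitter)
  models <- models %||% list(chronic_pain = model_spec("chronic_pain"),
                             high_impact = model_spec("high_impact"))
  check_flag(bootstrap_outcome %in% names(models),
             "bootstrap_outcome must be one of the modelled outcomes")
  cfg <- structure(list(output_dir = output_dir, seed = as.integer(seed),
                        geography = geography, truth = truth,
                        sampling = sampling, fitter = fitter, models = models,
                        bootstrap = bootstrap, bootstrap_outcome = bootstrap_outcome,
                        correction = correction, verbosity = verbosity),
                   class = "pipeline_config")
  cfg$hash <- substr(digest::digest(cfg[setdiff(names(cfg), "output_dir")]), 1, 12)
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Supports the scalar and flat-list settings (`seed`, `output_dir`,
#' `fitter`, `bootstrap_outcome`, `verbosity`, and the `sampling`,
#' `bootstrap` and `mcmc` blocks).  Structural settings — geography, ground
#' truth, priors — are R-level configuration via [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  mcmc <- y$mcmc %||% list()
  models <- list(chronic_pain = model_spec("chronic_pain", mcmc = mcmc),
                 high_impact = model_spec("high_impact", mcmc = mcmc))
  boot <- do.call(bootstrap_spec, y$bootstrap %||% list())
  args <- list(seed = y$seed %||% 1L, fitter = y$fitter %||% "approximate",
               models = models, bootstrap = boot, verbosity = y$verbosity %||% 1L,
               bootstrap_outcome = y$bootstrap_outcome %||% "high_impact")
  if (!is.null(y$output_dir)) args$output_dir <- y$output_dir
  if (!is.null(y$sampling)) args$sampling <- y$sampling
  do.call(pipeline_config, args)
}

PIPELINE_STAGES <- c("simulate", "preprocess", "fit", "poststratify",
                     "bootstrap", "inequality", "report")

pipe_msg <- function(cfg, fmt, ...) {
  if (cfg$verbosity > 0) message(sprintf("[painscape] %s", sprintf(fmt, ...)))
}

read_geography_dir <- function(dir) {
  structure(list(profiles = read_pain_csv(file.path(dir, "lsoa_profiles.csv")),
                 population = read_pain_csv(file.path(dir, "population.csv")),
                 ethnicity = read_pain_csv(file.path(dir, "ethnicity.csv"))),
            class = "pain_geography")
}

require_inputs <- function(dir, files, prior_stage) {
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing) > 0)
    stop_painscape("missing input(s) %s; run stage '%s' first",
                   paste(missing, collapse = ", "), prior_stage)
}

# serialize a fit to CSV rows (posterior summaries + centring constants)
fit_to_csv_rows <- function(fit, outcome) {
  tab <- fit$coefficients
  dg <- fit$diagnostics$table
  tab$ess <- if (is.null(dg)) NA_real_ else dg$ess[match(tab$parameter, dg$parameter)]
  tab$rhat <- if (is.null(dg)) NA_real_ else dg$rhat[match(tab$parameter, dg$parameter)]
  if (length(fit$centring) > 0)
    tab <- rbind(tab, data.frame(parameter = paste0("centring_", names(fit$centring)),
                                 mean = unname(fit$centring), sd = NA, q2.5 = NA,
                                 q97.5 = NA, ess = NA, rhat = NA))
  cbind(outcome = outcome, tab)
}

# rebuild a point-mass fit from model_fit.csv / random_effects.csv rows
fit_from_csv_rows <- function(fit_rows, re_rows, outcome) {
  fit_rows <- fit_rows[fit_rows$outcome == outcome, ]
  re_rows <- re_rows[re_rows$outcome == outcome, ]
  check_flag(nrow(fit_rows) > 0, "no stored fit for outcome '%s'", outcome)
  centring_rows <- grepl("^centring_", fit_rows$parameter)
  beta_rows <- !centring_rows & fit_rows$parameter != "sigma2_u"
  beta <- setNames(fit_rows$mean[beta_rows], fit_rows$parameter[beta_rows])
  design_stub <- list(lsoa_levels = re_rows$lsoa_code,
                      centring = setNames(fit_rows$mean[centring_rows],
                                          sub("^centring_", "", fit_rows$parameter[centring_rows])),
                      outcome = outcome)
  fit <- new_pain_fit("point_from_csv", design_stub,
                      matrix(beta, nrow = 1, dimnames = list(NULL, names(beta))),
                      matrix(re_rows$u_mean, nrow = 1,
                             dimnames = list(NULL, re_rows$lsoa_code)),
                      fit_rows$mean[fit_rows$parameter == "sigma2_u"])
  fit$term_names <- names(beta)
  fit
}

# corrected higher-level aggregates from corrected LSOA rows: population-
# weighted means of the LSOA estimates, so region/LA counts stay conserved
reaggregate_corrected <- function(lsoa_corrected, geography, level, outcome) {
  key <- switch(level,
                msoa = geography$profiles$msoa_code,
                la = geography$profiles$la_name,
                region = rep("region", nrow(geography$profiles)))
  i <- match(lsoa_corrected$geography_id, geography$profiles$lsoa_code)
  num <- tapply(lsoa_corrected$estimated_count, key[i], sum)
  den <- tapply(lsoa_corrected$population, key[i], sum)
  data.frame(geography_id = names(den), level = level, outcome = outcome,
             prevalence_percent = 100 * as.numeric(num) / as.numeric(den),
             estimated_count = as.numeric(num), population = as.numeric(den),
             stringsAsFactors = FALSE, row.names = NULL)
}

estimate_all_levels <- function(fit, geography, outcome, correction) {
  cells <- predict_cell_probabilities(fit, geography)
  unc <- do.call(rbind, lapply(c("lsoa", "msoa", "la", "region"),
                               function(lv) aggregate_prevalence(cells, geography, lv, outcome)))
  lsoa_cor <- apply_ethnicity_correction(
    unc[unc$level == "lsoa", ], geography, correction, outcome)
  cor_rows <- rbind(lsoa_cor[names(unc)],
                    do.call(rbind, lapply(c("msoa", "la", "region"), function(lv)
                      reaggregate_corrected(lsoa_cor, geography, lv, outcome))))
  unc$corrected <- FALSE
  cor_rows$corrected <- TRUE
  out <- rbind(unc, cor_rows)
  out$ci_lower <- NA_real_
  out$ci_upper <- NA_real_
  out[c("geography_id", "level", "outcome", "prevalence_percent",
        "ci_lower", "ci_upper", "corrected", "estimated_count", "population")]
}

#' Run the estimation pipeline
#'
#' Executes the requested stages in canonical order (simulate, preprocess,
#' fit, poststratify, bootstrap, inequality, report), reading any missing
#' stage inputs from `config$output_dir` so stages can be run separately.
#' Every output CSV carries a header comment with the config hash and seed;
#' rerunning with the same config is byte-identical.  When the poststratify
#' stage is run in a separate session from the fit stage, the stored fit is
#' reloaded as point estimates (posterior means), a documented limitation
#' relative to running both stages in one call with the MCMC fitter.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of the canonical stages.
#' @return invisibly, a list with the in-memory stage products.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  check_flag(all(stages %in% PIPELINE_STAGES), "unknown stage(s): %s",
             paste(setdiff(stages, PIPELINE_STAGES), collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- new.env(parent = emptyenv())

  geo <- function() {
    if (is.null(st$geography)) {
      require_inputs(dir, c("lsoa_profiles.csv", "population.csv", "ethnicity.csv"),
                     "simulate")
      st$geography <- read_geography_dir(dir)
    }
    st$geography
  }
  records <- function() {
    if (is.null(st$records)) {
      require_inputs(dir, "analysis_records.csv", "preprocess")
      r <- read_pain_csv(file.path(dir, "analysis_records.csv"))
      r$agesex <- factor(r$agesex, levels = AGESEX_LEVELS)
      st$records <- r
    }
    st$records
  }
  fit_of <- function(outcome) {
    if (is.null(st$fits)) {
      require_inputs(dir, c("model_fit.csv", "random_effects.csv"), "fit")
      fr <- read_pain_csv(file.path(dir, "model_fit.csv"))
      rr <- read_pain_csv(file.path(dir, "random_effects.csv"))
      st$fits <- setNames(lapply(names(config$models), fit_from_csv_rows,
                                 fit_rows = fr, re_rows = rr),
                          names(config$models))
    }
    st$fits[[outcome]]
  }

  for (stage in stages) {
    t0 <- Sys.time()
    switch(stage,
      simulate = {
        st$geography <- generate_geography(config$geography,
                                           seed = derive_seed(config$seed, 1L))
        st$survey <- generate_respondents(
          st$geography, config$truth,
          sampling_fraction = config$sampling$sampling_fraction,
          frame_coverage = config$sampling$frame_coverage,
          response_rate = config$sampling$response_rate,
          seed = derive_seed(config$seed, 2L))
        write_synthetic_data(st$geography, st$survey, dir, config$hash, config$seed)
        pipe_msg(config, "simulate: %d LSOAs, %d respondents",
                 nrow(st$geography$profiles), nrow(st$survey$respondents))
      },
      preprocess = {
        require_inputs(dir, "respondents.csv", "simulate")
        raw <- read_pain_csv(file.path(dir, "respondents.csv"))
        rec <- make_analysis_records(raw)
        fc <- filter_complete_cases(rec)
        write_pain_csv(fc$kept, file.path(dir, "analysis_records.csv"),
                       config$hash, config$seed)
        pipe_msg(config, "preprocess: kept %d complete cases, dropped %d (required: agesex, chronic_pain, high_impact)",
                 nrow(fc$kept), fc$dropped)
        st$records <- fc$kept
      },
      fit = {
        st$fits <- list()
        fit_rows <- list(); re_rows <- list()
        rec <- records()
        g <- geo()
        for (outcome in names(config$models)) {
          design <- build_design(rec, g, config$models[[outcome]])
          fit <- if (config$fitter == "mcmc") fit_mcmc(design)
                 else fit_approximate(design)
          st$fits[[outcome]] <- fit
          fit_rows[[outcome]] <- fit_to_csv_rows(fit, outcome)
          re_rows[[outcome]] <- data.frame(
            outcome = outcome, lsoa_code = fit$lsoa_levels,
            u_mean = colMeans(fit$u_draws),
            u_sd = apply(fit$u_draws, 2, sd), row.names = NULL)
          pipe_msg(config, "fit (%s, %s): sigma2_u = %.4f",
                   outcome, config$fitter, mean(fit$sigma2_draws))
        }
        write_pain_csv(do.call(rbind, fit_rows), file.path(dir, "model_fit.csv"),
                       config$hash, config$seed)
        write_pain_csv(do.call(rbind, re_rows), file.path(dir, "random_effects.csv"),
                       config$hash, config$seed)
      },
      poststratify = {
        est <- do.call(rbind, lapply(names(config$models), function(outcome)
          estimate_all_levels(fit_of(outcome), geo(), outcome, config$correction)))
        write_pain_csv(est, file.path(dir, "estimates.csv"), config$hash, config$seed)
        st$estimates <- est
        pipe_msg(config, "poststratify: %d estimate rows", nrow(est))
      },
      bootstrap = {
        boot <- config$bootstrap
        boot$seed <- derive_seed(config$seed, 4L)
        cis <- bootstrap_estimates(records(), geo(),
                                   config$models[[config$bootstrap_outcome]],
                                   boot, config$correction)
        write_pain_csv(cis, file.path(dir, "bootstrap_cis.csv"),
                       config$hash, config$seed)
        st$bootstrap <- cis
        if (!is.null(st$estimates)) {
          sel <- st$estimates$level == "lsoa" & st$estimates$corrected &
            st$estimates$outcome == config$bootstrap_outcome
          i <- match(st$estimates$geography_id[sel], cis$lsoa_code)
          st$estimates$ci_lower[sel] <- cis$ci_lower[i]
          st$estimates$ci_upper[sel] <- cis$ci_upper[i]
          write_pain_csv(st$estimates, file.path(dir, "estimates.csv"),
                         config$hash, config$seed)
        }
        pipe_msg(config, "bootstrap: %d replicates, %d failed (%s)",
                 boot$n_replicates, attr(cis, "n_failed"), config$bootstrap_outcome)
      },
      inequality = {
        if (is.null(st$estimates)) {
          require_inputs(dir, "estimates.csv", "poststratify")
          st$estimates <- read_pain_csv(file.path(dir, "estimates.csv"))
        }
        ineq <- do.call(rbind, lapply(names(config$models), function(outcome) {
          e <- st$estimates[st$estimates$level == "lsoa" & st$estimates$corrected &
                              st$estimates$outcome == outcome, ]
          inequality_summary(data.frame(lsoa_code = e$geography_id,
                                        prevalence_percent = e$prevalence_percent),
                             geo(), outcome)
        }))
        write_pain_csv(ineq, file.path(dir, "inequality.csv"), config$hash, config$seed)
        st$inequality <- ineq
        pipe_msg(config, "inequality: %d LA x outcome rows", nrow(ineq))
      },
      report = {
        txt <- render_report(records(), st, dir, config)
        writeLines(txt, file.path(dir, "report.txt"))
        if (config$verbosity > 0) cat(txt, sep = "\n")
      })
    pipe_msg(config, "stage '%s' done in %.1fs", stage,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  invisible(as.list(st))
}

#' Crude prevalence table in survey-report layout
#'
#' One row per age-sex category with respondent counts and the number (and
#' whole-percent share) reporting each outcome — display rounding only; the
#' underlying computation is exact.
#'
#' @param records complete-case analysis records.
#' @return data.frame with formatted count (percent) columns.
#' @export
format_crude_table <- function(records) {
  cp <- crude_prevalence(records, "chronic_pain", by = "agesex")
  hi <- crude_prevalence(records, "high_impact", by = "agesex")
  data.frame(agesex = cp$group, respondents = cp$denominator,
             chronic_pain = sprintf("%d (%d)", cp$numerator, round(cp$percent)),
             high_impact = sprintf("%d (%d)", hi$numerator, round(hi$percent)),
             stringsAsFactors = FALSE)
}

render_report <- function(records, st, dir, config) {
  lines <- c("painscape run report",
             sprintf("config hash %s, seed %d", config$hash, config$seed), "",
             "Respondents and outcomes by age-sex category (count (%)):")
  ct <- format_crude_table(records)
  lines <- c(lines, utils::capture.output(print(ct, row.names = FALSE)))
  if (is.null(st$inequality) && file.exists(file.path(dir, "inequality.csv")))
    st$inequality <- read_pain_csv(file.path(dir, "inequality.csv"))
  if (!is.null(st$inequality)) {
    ineq <- st$inequality
    for (col in c("twenty_twenty", "twenty_twenty_signed"))
      ineq[[col]] <- round(ineq[[col]], 2)
    for (col in c("median_percent", "min_percent", "max_percent", "fold_variation"))
      ineq[[col]] <- round(ineq[[col]], 1)
    lines <- c(lines, "", "Neighbourhood inequality by local authority:",
               utils::capture.output(print(ineq, row.names = FALSE)))
  }
  lines
}
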