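#' Write a pipeline CSV with a provenance header
#'
#' All interchange tables are plain CSV with a single leading `#` comment
#' line carrying the config hash and seed, so outputs are auditable and
#' byte-identical across reruns of the same configuration.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param config_hash,seed optional provenance values for the header.
#' @return invisibly, `path`.
#' @export
write_pain_csv <- function(df, path, config_hash = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# painscape config_hash=%s seed=%s",
                     config_hash %||% "NA", seed %||% "NA"), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV
#'
#' @param path CSV path (leading `#` comment lines are skipped).
#' @return data.frame.
#' @export
read_pain_csv <- function(path) {
  check_flag(file.exists(path), "file not found: %s", path)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# closed-vocabulary / range checks per schema; each entry is
# list(required_numeric_or_categorical_constraints)
pain_schemas <- function() {
  list(
    lsoa_profiles = list(
      columns = c("lsoa_code", "msoa_code", "la_name", "imd_decile", "rural_flag"),
      vocab = list(rural_flag = 0:1, imd_decile = 1:10)),
    population = list(
      columns = c("lsoa_code", "sex", "age_group", "count"),
      vocab = list(sex = SEXES, age_group = AGE_GROUPS),
      numeric = list(count = c(0, Inf))),
    ethnicity = list(
      columns = c("lsoa_code", ETHNIC_GROUPS),
      numeric = setNames(rep(list(c(0, 1)), 5), ETHNIC_GROUPS),
      row_sum = list(cols = ETHNIC_GROUPS, total = 1, tol = 1e-6)),
    respondents = list(
      columns = c("respondent_id", "lsoa_code", "sex", "age_years",
                  "chronic_pain", "high_impact", paste0("hads_d", 1:7),
                  "weight_kg", "height_m"),
      vocab = c(list(sex = SEXES, chronic_pain = 0:1, high_impact = 0:1),
                setNames(rep(list(0:3), 7), paste0("hads_d", 1:7))),
      numeric = list(age_years = c(35, Inf), weight_kg = c(1e-9, Inf),
                     height_m = c(1e-9, Inf))),
    estimates = list(
      columns = c("geography_id", "level", "outcome", "prevalence_percent",
                  "ci_lower", "ci_upper", "corrected", "estimated_count"),
      vocab = list(level = c("lsoa", "msoa", "la", "region"),
                   outcome = OUTCOMES),
      numeric = list(prevalence_percent = c(0, 100)))
  )
}

#' Validate a CSV against a pipeline schema
#'
#' Checks column presence, closed category vocabularies (sex, age groups,
#' deciles, outcome levels, ...) and numeric ranges, returning every
#' violation found — each naming the file, row and column — rather than
#' stopping at the first.
#'
#' @param file CSV path.
#' @param schema_name one of `"lsoa_profiles"`, `"population"`,
#'   `"ethnicity"`, `"respondents"`, `"estimates"`.
#' @return character vector of violations; `character(0)` means the file is
#'   valid.
#' @export
validate_schema <- function(file, schema_name) {
  schemas <- pain_schemas()
  check_flag(schema_name %in% names(schemas), "unknown schema '%s'", schema_name)
  df <- tryCatch(read_pain_csv(file),
                 error = function(e) stop_painscape("cannot read %s: %s",
                                                    file, conditionMessage(e)))
  sch <- schemas[[schema_name]]
  errs <- character(0)
  missing_cols <- setdiff(sch$columns, names(df))
  if (length(missing_cols) > 0)
    errs <- c(errs, sprintf("%s: missing column '%s'", file, missing_cols))

  for (col in names(sch$vocab %||% list())) {
    if (!col %in% names(df)) next
    bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% sch$vocab[[col]]))
    errs <- c(errs, sprintf("%s: row %d, column '%s': invalid value '%s'",
                            file, bad, col, df[[col]][bad]))
  }
  for (col in names(sch$numeric %||% list())) {
    if (!col %in% names(df)) next
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) &
                   (is.na(v) | v < sch$numeric[[col]][1] | v > sch$numeric[[col]][2]))
    errs <- c(errs, sprintf("%s: row %d, column '%s': out of range or non-numeric '%s'",
                            file, bad, col, df[[col]][bad]))
  }
  rs <- sch$row_sum
  if (!is.null(rs) && all(rs$cols %in% names(df))) {
    tot <- rowSums(as.matrix(df[rs$cols]))
    bad <- which(abs(tot - rs$total) > rs$tol)
    errs <- c(errs, sprintf("%s: row %d (%s): columns %s sum to %.6f, expected %g",
                            file, bad, df$lsoa_code[bad] %||% "?",
                            paste(rs$cols, collapse = "+"), tot[bad], rs$total))
  }
  errs
}
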