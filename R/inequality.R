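#' Assign region-wide prevalence quintiles to LSOAs
#'
#' LSOAs are ranked ascending by estimate across the whole region and split
#' into five rank-based groups as equal as possible (sizes differ by at most
#' one, with the larger groups lowest; 298 LSOAs split 60/60/60/59/59).
#' Ties are broken deterministically by LSOA code.  Quintile 1 holds the
#' lowest-prevalence LSOAs.  Rank-based assignment (rather than value
#' cut-points) guarantees the balanced group sizes "quintile" implies,
#' regardless of ties.
#'
#' @param lsoa_estimates data.frame with lsoa_code and a `prevalence_percent`
#'   (or `value`) column, or a named numeric vector.
#' @return data.frame: lsoa_code, quintile (integer 1-5).
#' @export
assign_quintiles <- function(lsoa_estimates) {
  if (is.numeric(lsoa_estimates)) {
    lsoa_estimates <- data.frame(lsoa_code = names(lsoa_estimates),
                                 value = unname(lsoa_estimates),
                                 stringsAsFactors = FALSE)
  }
  val <- lsoa_estimates$prevalence_percent %||% lsoa_estimates$value
  code <- lsoa_estimates$lsoa_code %||% lsoa_estimates$geography_id
  check_flag(!is.null(code), "lsoa_estimates must carry lsoa_code (or geography_id)")
  n <- length(val)
  check_flag(n >= 5, "quintile assignment needs at least 5 LSOAs (got %d)", n)
  ord <- order(val, code)
  sizes <- rep(n %/% 5L, 5L)
  extra <- n %% 5L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  q <- integer(n)
  q[ord] <- rep(1:5, times = sizes)
  data.frame(lsoa_code = code, quintile = q, stringsAsFactors = FALSE)
}

#' The 20:20 neighbourhood inequality metric
#'
#' Within a local authority: (number of LSOAs in the region's highest
#' prevalence quintile minus number in the lowest quintile) divided by the
#' LA's total LSOA count — a rank-based measure of how concentrated the
#' extremes of the regional distribution are in that authority.  The
#' absolute value is returned (published tables print the magnitude even
#' where low-quintile LSOAs dominate and the raw difference is negative);
#' the signed value is retained as a column by [inequality_summary()].
#'
#' @param n_highest,n_lowest LSOA counts in the highest/lowest quintile.
#' @param n_total total LSOAs in the authority (> 0).
#' @return `|n_highest - n_lowest| / n_total`, in `[0, 1]`.
#' @export
twenty_twenty <- function(n_highest, n_lowest, n_total) {
  check_flag(all(n_total > 0), "n_total must be positive")
  check_flag(all(n_highest + n_lowest <= n_total),
             "quintile counts cannot exceed the total LSOA count")
  abs(n_highest - n_lowest) / n_total
}

#' Median, range and fold-variation of a set of estimates
#'
#' @param values numeric prevalences (non-empty).
#' @return data.frame: median (linear-interpolation definition), min, max,
#'   fold (max/min; `NA` with a warning when min is 0, where fold variation
#'   is undefined).
#' @export
summarize_distribution <- function(values) {
  check_flag(length(values) >= 1 && all(is.finite(values)),
             "values must be non-empty and finite")
  fold <- if (min(values) == 0) {
    warning("minimum is 0: fold variation undefined", call. = FALSE)
    NA_real_
  } else max(values) / min(values)
  data.frame(median = median(values), min = min(values), max = max(values),
             fold = fold)
}

#' Per-local-authority inequality summary
#'
#' Reproduces the published-table layout: for each LA, the LSOA count, the
#' counts in the region-wide lowest and highest prevalence quintiles, the
#' 20:20 metric (absolute convention, with the signed value alongside), and
#' the median, range and fold-variation of its LSOA estimates.
#'
#' @param lsoa_estimates LSOA-level estimates: data.frame with lsoa_code and
#'   prevalence_percent.
#' @param geography the study geography (maps LSOAs to LAs).
#' @param outcome label recorded in the output.
#' @return data.frame of class `inequality_summary`, one row per LA.
#' @export
inequality_summary <- function(lsoa_estimates, geography, outcome = "chronic_pain") {
  profiles <- geography$profiles
  if (is.null(lsoa_estimates$lsoa_code))
    lsoa_estimates$lsoa_code <- lsoa_estimates$geography_id
  q <- assign_quintiles(lsoa_estimates)
  m <- merge(merge(lsoa_estimates, q, by = "lsoa_code"),
             profiles[c("lsoa_code", "la_name")], by = "lsoa_code")
  las <- unique(profiles$la_name)
  rows <- lapply(las, function(la) {
    g <- m[m$la_name == la, ]
    n_low <- sum(g$quintile == 1)
    n_high <- sum(g$quintile == 5)
    dist <- summarize_distribution(g$prevalence_percent)
    data.frame(la_name = la, outcome = outcome, n_lsoas = nrow(g),
               n_lowest_quintile = n_low, n_highest_quintile = n_high,
               twenty_twenty = twenty_twenty(n_high, n_low, nrow(g)),
               twenty_twenty_signed = (n_high - n_low) / nrow(g),
               median_percent = dist$median, min_percent = dist$min,
               max_percent = dist$max, fold_variation = dist$fold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("inequality_summary", class(out))
  out
}
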