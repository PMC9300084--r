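#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stability analysis
#'
#' Returns the facility-level stability table (one row per measure, or per
#' measure and tier with `by_tier = TRUE`): pair counts, mean absolute and
#' net change, design-weighted Pearson correlation and its strength band,
#' percent agreement and Cohen's kappa of tertile classifications.
#'
#' @param x a `qualstab_stability` object.
#' @param by_tier return the tier-stratified table instead.
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.qualstab_stability <- function(x, by_tier = FALSE, ...) {
  if (by_tier) x$by_tier else x$facility
}

#' One-row summary of a stability analysis
#'
#' @param x a `qualstab_stability` object.
#' @param ... unused.
#' @return A tibble with the number of measures and pairs analysed and the
#'   median facility-level correlation, kappa and regional correlation.
#' @exportS3Method generics::glance
glance.qualstab_stability <- function(x, ...) {
  tibble::tibble(
    n_measures = nrow(x$facility),
    n_pairs_max = max(x$facility$n),
    median_facility_r = median(x$facility$pearson_r, na.rm = TRUE),
    median_kappa = median(x$facility$kappa, na.rm = TRUE),
    median_regional_r = median(x$regional$pearson_r, na.rm = TRUE))
}

#' Tidy pipeline coverage results
#'
#' @param x a `qualstab_pipeline` object.
#' @param ... unused.
#' @return The per-estimate coverage difference table.
#' @exportS3Method generics::tidy
tidy.qualstab_pipeline <- function(x, ...) {
  x$coverage_differences
}

#' One-row summary of a pipeline run
#'
#' @param x a `qualstab_pipeline` object.
#' @param ... unused.
#' @return A tibble with pair counts and the national and regional median
#'   relative differences in adjusted coverage.
#' @exportS3Method generics::glance
glance.qualstab_pipeline <- function(x, ...) {
  d <- x$coverage_differences
  tibble::tibble(
    n_pairs = dplyr::n_distinct(paste(x$pairs$facility_id, x$pairs$wave_t0)),
    n_estimates = nrow(d),
    national_median_relative_diff_pct = median(
      d$relative_diff_pct[d$level == "national"], na.rm = TRUE),
    regional_median_relative_diff_pct = median(
      d$relative_diff_pct[d$level == "major_region"], na.rm = TRUE))
}
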