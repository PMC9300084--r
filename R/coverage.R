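# Adjusted (effective) coverage: contact coverage from household records,
# linked to facility quality by source-type strata, for the reference-period
# SPA and the same facilities assessed two years earlier.

#' Service-to-quality-measure mapping
#'
#' Which quality measure discounts which service: ANC 1 and ANC 4 use ANC
#' readiness (input-adjusted) and ANC adherence (quality-adjusted); facility
#' delivery uses basic obstetric readiness and the BEmONC signal-function
#' proportion; sick-child care uses child readiness and child adherence.
#'
#' @return A tibble: `service`, `adjustment`
#'   (`input_adjusted`/`quality_adjusted`), `measure`.
#' @export
service_measure_map <- function() {
  tibble::tribble(
    ~service,   ~adjustment,        ~measure,
    "ANC1",     "input_adjusted",   "readiness_anc",
    "ANC1",     "quality_adjusted", "process_anc",
    "ANC4",     "input_adjusted",   "readiness_anc",
    "ANC4",     "quality_adjusted", "process_anc",
    "delivery", "input_adjusted",   "readiness_obstetric",
    "delivery", "quality_adjusted", "process_obstetric_signal",
    "child",    "input_adjusted",   "readiness_child",
    "child",    "quality_adjusted", "process_child")
}

#' Assign a single source type from reported sources
#'
#' Women reporting multiple ANC sources are assigned the highest reported
#' facility type in the order public hospital > public health centre >
#' public health post > private. Health huts, unclassifiable facilities and
#' empty reports are assigned `"none"` (not receiving services). Unknown
#' tokens are an error.
#'
#' @param sources character vector; multiple sources separated by `";"`.
#'   `NA` and `""` yield `"none"`.
#' @return Character vector over `public_hospital`, `public_health_centre`,
#'   `public_health_post`, `private`, `none`.
#' @examples
#' assign_source_type(c("public_health_post;public_hospital",
#'                      "health_hut_or_unknown", "private"))
#' @export
assign_source_type <- function(sources) {
  parts <- strsplit(ifelse(is.na(sources), "", sources), ";", fixed = TRUE)
  vapply(parts, function(s) {
    s <- s[nzchar(s)]
    bad <- setdiff(s, SOURCE_TYPES)
    if (length(bad) > 0) {
      abort(paste0("unknown source token(s): ", paste(bad, collapse = ", ")))
    }
    ranks <- match(s, SOURCE_HIERARCHY)
    if (all(is.na(ranks))) "none" else SOURCE_HIERARCHY[min(ranks, na.rm = TRUE)]
  }, character(1))
}

# Per-unit service use: the assigned source type (or "none") under each
# service's eligibility rule.
household_service_use <- function(households, service) {
  h <- households
  if (service %in% c("ANC1", "ANC4")) {
    h <- h[h$unit_type == "woman_live_birth_2y", ]
    src <- assign_source_type(h$anc_sources)
    min_visits <- if (service == "ANC4") 4L else 1L
    src[is.na(h$anc_visits) | h$anc_visits < min_visits] <- "none"
  } else if (service == "delivery") {
    h <- h[h$unit_type == "woman_live_birth_2y", ]
    src <- assign_source_type(h$delivery_source)
  } else if (service == "child") {
    h <- h[h$unit_type == "child_under5_symptomatic_2w", ]
    src <- assign_source_type(h$child_source)
  } else {
    abort(sprintf("unknown service `%s`", service))
  }
  tibble::tibble(major_region = h$major_region, survey_year = h$survey_year,
                 source_type = src, survey_weight = h$survey_weight)
}

#' Survey-weighted source-type shares among those in need
#'
#' The share of the in-need population using each facility type (and none),
#' per survey year, nationally or by major region. Contact coverage is the
#' sum of the facility-type shares.
#'
#' @param households household table from [simulate_households()] or
#'   equivalent.
#' @param service one of `"ANC1"`, `"ANC4"`, `"delivery"`, `"child"`.
#' @param level `"national"` or `"major_region"`.
#' @return A tibble: `level`, `stratum` (`"national"` or the region),
#'   `survey_year`, `source_type`, `share`.
#' @export
source_type_shares <- function(households, service,
                               level = c("national", "major_region")) {
  level <- match.arg(level)
  use <- household_service_use(households, service)
  use$stratum <- if (level == "national") "national" else use$major_region
  tot <- dplyr::summarise(
    dplyr::group_by(use, .data$stratum, .data$survey_year),
    total_w = sum(.data$survey_weight), .groups = "drop")
  shares <- dplyr::summarise(
    dplyr::group_by(use, .data$stratum, .data$survey_year, .data$source_type),
    w = sum(.data$survey_weight), .groups = "drop")
  shares <- dplyr::left_join(shares, tot, by = c("stratum", "survey_year"))
  grid <- tidyr::crossing(
    dplyr::distinct(tot[, c("stratum", "survey_year")]),
    source_type = c(SOURCE_HIERARCHY, "none"))
  out <- dplyr::left_join(grid, shares, by = c("stratum", "survey_year",
                                               "source_type"))
  out$share <- ifelse(is.na(out$w), 0, out$w / out$total_w)
  out$level <- level
  out[, c("level", "stratum", "survey_year", "source_type", "share")]
}

#' Contact coverage
#'
#' Survey-weighted share of the in-need population whose assigned source is
#' a hospital, health centre, health post or private facility (with at
#' least 1 or 4 visits for ANC 1 and ANC 4).
#'
#' @inheritParams source_type_shares
#' @return A tibble: `level`, `stratum`, `survey_year`, `contact_coverage`.
#' @export
contact_coverage <- function(households, service,
                             level = c("national", "major_region")) {
  sh <- source_type_shares(households, service, level)
  dplyr::summarise(
    dplyr::group_by(sh, .data$level, .data$stratum, .data$survey_year),
    contact_coverage = sum(.data$share[.data$source_type != "none"]),
    .groups = "drop")
}

#' SPA reference wave for a household survey year
#'
#' Maternal services (ANC 1, ANC 4, facility delivery) are matched to the
#' facility assessment one year prior to the household interview year (a
#' 2018 interview about pregnancies in the past two years maps to the 2017
#' assessment); child services are matched to the same year.
#'
#' @param service service name.
#' @param household_year DHS interview year(s).
#' @return Integer wave year(s).
#' @examples
#' reference_wave("delivery", 2018)
#' reference_wave("child", 2016)
#' @export
reference_wave <- function(service, household_year) {
  stopifnot(all(service %in% SERVICES))
  ifelse(service %in% c("ANC1", "ANC4", "delivery"),
         as.integer(household_year) - 1L, as.integer(household_year))
}

# Facility source type: public facilities keep their tier; all private
# facilities pool into one "private" stratum.
facility_source_type <- function(tier, authority) {
  ifelse(authority == "private", "private",
         c(hospital = "public_hospital",
           health_centre = "public_health_centre",
           health_post = "public_health_post")[tier])
}

#' Facility-weighted mean quality per source-type stratum
#'
#' Averages a quality measure over the facilities of each source type
#' (private facilities of any tier pooled), weighted by the facility design
#' weight, nationally or within major regions. Empty cells yield no row and
#' feed the eligibility filter of [estimate_adjusted_coverage()].
#'
#' @param scores long score table restricted to the facilities and wave of
#'   interest.
#' @param facilities facility metadata (`facility_id`, `wave`, `tier`,
#'   `authority`, `major_region`, `facility_weight`).
#' @param measure quality measure name.
#' @param wave SPA wave year.
#' @param level `"national"` or `"major_region"`.
#' @return A tibble: `stratum`, `source_type`, `quality`, `n_facilities`.
#' @export
stratum_quality <- function(scores, facilities, measure, wave,
                            level = c("national", "major_region")) {
  level <- match.arg(level)
  s <- scores[scores$measure == measure & scores$wave == wave &
                !is.na(scores$value), ]
  d <- dplyr::inner_join(
    s, facilities[facilities$wave == wave,
                  c("facility_id", "wave", "tier", "authority",
                    "major_region", "facility_weight")],
    by = c("facility_id", "wave"))
  d$source_type <- facility_source_type(d$tier, d$authority)
  d$stratum <- if (level == "national") "national" else d$major_region
  dplyr::summarise(
    dplyr::group_by(d, .data$stratum, .data$source_type),
    quality = wmean(.data$value, .data$facility_weight),
    n_facilities = dplyr::n(),
    .groups = "drop")
}

#' Input- and quality-adjusted coverage estimates
#'
#' For each service, adjustment measure, level stratum and household survey
#' year, computes adjusted coverage as the sum over facility types of the
#' in-need share using that type times the type's mean quality -- the
#' product of contact coverage and quality when quality is constant.
#' Quality comes from the paired analytic panel: the `"t"` reference uses
#' facilities assessed in the service's reference-period wave that were also
#' assessed two years earlier, and the `"t_minus_2"` reference uses the same
#' facilities' earlier assessment. Regional estimates are kept only when the
#' region has at least one facility of every type respondents reported
#' using (`eligible`); household years whose reference wave has no paired
#' assessments are skipped with a warning.
#'
#' @param households household table.
#' @param pairs paired panel from [pair_assessments()].
#' @param scores long score table covering both waves of the pairs.
#' @param mapping service-measure mapping, see [service_measure_map()].
#' @param levels levels to estimate (`"national"`, `"major_region"`).
#' @return A tibble with one row per service, adjustment measure, stratum,
#'   household year and SPA reference: `contact_coverage`,
#'   `adjusted_value`, `eligible`.
#' @export
estimate_adjusted_coverage <- function(households, pairs, scores,
                                       mapping = service_measure_map(),
                                       levels = c("national", "major_region")) {
  hh_years <- sort(unique(households$survey_year))
  out <- list()
  for (i in seq_len(nrow(mapping))) {
    service <- mapping$service[i]
    measure <- mapping$measure[i]
    for (level in levels) {
      shares_all <- source_type_shares(households, service, level)
      for (yr in hh_years) {
        ref <- reference_wave(service, yr)
        panel <- pairs[pairs$wave_t1 == ref, ]
        if (nrow(panel) == 0L) {
          warn(sprintf(
            "no paired assessments with reference wave %d (service %s, year %d): skipped",
            ref, service, yr))
          next
        }
        shares <- shares_all[shares_all$survey_year == yr, ]
        for (spa_ref in c("t", "t_minus_2")) {
          wv <- if (spa_ref == "t") ref else ref - 2L
          wcol <- if (spa_ref == "t") "weight_t1" else "weight_t0"
          fac <- tibble::tibble(
            facility_id = panel$facility_id, wave = wv,
            tier = panel$tier,
            authority = panel_authority(panel),
            major_region = panel$major_region,
            facility_weight = panel[[wcol]])
          sq <- stratum_quality(scores, fac, measure, wv, level)
          est <- adjusted_from_shares(shares, sq)
          est$service <- service
          est$adjustment <- mapping$adjustment[i]
          est$measure <- measure
          est$level <- level
          est$household_year <- yr
          est$spa_reference <- spa_ref
          out[[length(out) + 1L]] <- est
        }
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res[, c("service", "adjustment", "measure", "level", "stratum",
          "household_year", "spa_reference", "contact_coverage",
          "adjusted_value", "eligible")]
}

# `pairs` does not carry authority; recover it from the facility id when the
# generator produced it, else assume public (user-supplied panels should
# include an `authority` column).
panel_authority <- function(panel) {
  if ("authority" %in% names(panel)) panel$authority else "public"
}

# Combine in-need source-type shares with stratum qualities:
# adjusted = sum_type share_type * quality_type; ineligible if a used type
# has no facility in the cell.
adjusted_from_shares <- function(shares, sq) {
  strata <- unique(shares$stratum)
  purrr::map_dfr(strata, function(st) {
    sh <- shares[shares$stratum == st & shares$source_type != "none", ]
    q <- sq[sq$stratum == st, ]
    m <- dplyr::left_join(sh, q[, c("source_type", "quality")],
                          by = "source_type")
    used <- m$share > 0
    eligible <- all(!is.na(m$quality[used]))
    tibble::tibble(
      stratum = st,
      contact_coverage = sum(m$share),
      adjusted_value = if (eligible) sum(m$share[used] * m$quality[used])
        else NA_real_,
      eligible = eligible)
  })
}

#' Differences between adjusted coverage built two years apart
#'
#' Pairs each `"t"` estimate with its `"t_minus_2"` twin and computes the
#' linear difference in percentage points, `100 * |E_t - E_t2|`, and the
#' relative difference in percent, `100 * |E_t - E_t2| / E_t` (undefined
#' when `E_t` is 0). Signed versions are kept for plotting.
#'
#' @param estimates output of [estimate_adjusted_coverage()].
#' @return A tibble with one row per estimate pair, including
#'   `linear_diff_pp`, `relative_diff_pct` and their signed counterparts.
#' @export
compare_adjusted_coverage <- function(estimates) {
  keys <- c("service", "adjustment", "measure", "level", "stratum",
            "household_year")
  e_t <- estimates[estimates$spa_reference == "t", ]
  e_2 <- estimates[estimates$spa_reference == "t_minus_2",
                   c(keys, "adjusted_value")]
  d <- dplyr::inner_join(e_t, dplyr::rename(e_2, value_t2 = "adjusted_value"),
                         by = keys)
  d <- d[!is.na(d$adjusted_value) & !is.na(d$value_t2), ]
  d$signed_linear_diff_pp <- 100 * (d$adjusted_value - d$value_t2)
  d$linear_diff_pp <- abs(d$signed_linear_diff_pp)
  d$signed_relative_diff_pct <- ifelse(
    d$adjusted_value > 0,
    100 * (d$adjusted_value - d$value_t2) / d$adjusted_value, NA_real_)
  d$relative_diff_pct <- abs(d$signed_relative_diff_pct)
  if (any(d$adjusted_value == 0)) {
    warn("relative difference undefined where the reference estimate is 0")
  }
  d[, c(keys, "contact_coverage", "adjusted_value", "value_t2",
        "linear_diff_pp", "relative_diff_pct", "signed_linear_diff_pp",
        "signed_relative_diff_pct")]
}

#' Median and IQR summary of coverage differences
#'
#' Summarises contact coverage, adjusted coverage and the absolute linear
#' and relative differences as median (IQR) across estimates, per service
#' and adjustment measure -- the shape of a regional difference table -- at
#' the requested level.
#'
#' @param differences output of [compare_adjusted_coverage()].
#' @param level which level's estimates to summarise.
#' @return A tibble per service-measure with `n` and median/IQR columns (in
#'   percent for coverage, percentage points and percent for differences).
#' @export
summarise_coverage_differences <- function(differences,
                                           level = c("major_region",
                                                     "national")) {
  level <- match.arg(level)
  d <- differences[differences$level == level, ]
  q <- function(x, p) unname(quantile(x, p, na.rm = TRUE, type = 7))
  dplyr::summarise(
    dplyr::group_by(d, .data$service, .data$adjustment, .data$measure),
    n = dplyr::n(),
    coverage_median = 100 * median(.data$contact_coverage),
    coverage_q1 = 100 * q(.data$contact_coverage, 0.25),
    coverage_q3 = 100 * q(.data$contact_coverage, 0.75),
    adjusted_median = 100 * median(.data$adjusted_value),
    adjusted_q1 = 100 * q(.data$adjusted_value, 0.25),
    adjusted_q3 = 100 * q(.data$adjusted_value, 0.75),
    linear_diff_median = median(.data$linear_diff_pp),
    linear_diff_q1 = q(.data$linear_diff_pp, 0.25),
    linear_diff_q3 = q(.data$linear_diff_pp, 0.75),
    relative_diff_median = median(.data$relative_diff_pct, na.rm = TRUE),
    relative_diff_q1 = q(.data$relative_diff_pct, 0.25),
    relative_diff_q3 = q(.data$relative_diff_pct, 0.75),
    .groups = "drop")
}
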