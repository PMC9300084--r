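# Stability analysis: pairing assessments two years apart, paired
# differences, design-weighted Pearson correlation, percent agreement and
# Cohen's kappa on tertile classifications, and regional aggregation.

#' Pair assessments of the same facility two years apart
#'
#' Emits every (t, t+2) pair of waves observed for a facility; a facility
#' assessed in three eligible waves contributes two pairs and carries its
#' facility id as a cluster id for cluster-aware downstream use.
#'
#' @param facilities facility table with one row per facility-wave
#'   (`facility_id`, `wave`, `tier`, `major_region`, `facility_weight`, ...).
#' @param gap wave gap in years (2 by design).
#' @return A tibble: `facility_id`, `cluster_id`, `pair_set`
#'   (`"t0-t1"` label), `wave_t0`, `wave_t1`, `tier`, `major_region`,
#'   `weight_t0`, `weight_t1`.
#' @examples
#' fac <- tibble::tibble(facility_id = "a", wave = c(2014, 2016, 2018),
#'                       tier = "hospital", major_region = "West",
#'                       facility_weight = 2)
#' pair_assessments(fac)
#' @export
pair_assessments <- function(facilities, gap = 2) {
  dup <- duplicated(facilities[, c("facility_id", "wave")])
  if (any(dup)) {
    offenders <- unique(paste0(facilities$facility_id[dup], " @ ",
                               facilities$wave[dup]))
    abort(paste0("duplicate facility-wave rows: ",
                 paste(utils::head(offenders, 5), collapse = ", "),
                 if (length(offenders) > 5) " ..."))
  }
  t0 <- dplyr::mutate(facilities, wave_next = .data$wave + gap)
  pairs <- dplyr::inner_join(
    t0, facilities,
    by = c("facility_id", "wave_next" = "wave"),
    suffix = c("_t0", "_t1"))
  tibble::tibble(
    facility_id = pairs$facility_id,
    cluster_id = pairs$facility_id,
    pair_set = paste0(pairs$wave, "-", pairs$wave_next),
    wave_t0 = pairs$wave, wave_t1 = pairs$wave_next,
    tier = pairs$tier_t0, major_region = pairs$major_region_t0,
    authority = if ("authority_t0" %in% names(pairs)) pairs$authority_t0
      else "public",
    weight_t0 = pairs$facility_weight_t0,
    weight_t1 = pairs$facility_weight_t1)
}

#' Attach scores (and tertiles) at both waves of each pair
#'
#' For each measure, keeps only pairs with a non-missing score at both
#' waves; those pairs are the unit of the stability analysis.
#'
#' @param pairs output of [pair_assessments()].
#' @param scores long score table from [score_facilities()].
#' @param tertiles optional tertile table from [classify_tertiles()].
#' @return A tibble with one row per pair-measure: pair metadata plus
#'   `score_t0`, `score_t1` and (if tertiles given) `tertile_t0`,
#'   `tertile_t1`.
#' @export
paired_scores <- function(pairs, scores, tertiles = NULL) {
  s <- scores[!is.na(scores$value), c("facility_id", "wave", "measure", "value")]
  out <- dplyr::inner_join(
    pairs, dplyr::rename(s, wave_t0 = "wave", score_t0 = "value"),
    by = c("facility_id", "wave_t0"))
  out <- dplyr::inner_join(
    out, dplyr::rename(s, wave_t1 = "wave", score_t1 = "value"),
    by = c("facility_id", "wave_t1", "measure"))
  if (!is.null(tertiles)) {
    tt <- tertiles[, c("facility_id", "wave", "measure", "tertile")]
    out <- dplyr::left_join(
      out, dplyr::rename(tt, wave_t0 = "wave", tertile_t0 = "tertile"),
      by = c("facility_id", "wave_t0", "measure"))
    out <- dplyr::left_join(
      out, dplyr::rename(tt, wave_t1 = "wave", tertile_t1 = "tertile"),
      by = c("facility_id", "wave_t1", "measure"))
  }
  out
}

#' Design-weighted Pearson correlation
#'
#' \eqn{r = \sum w (x-\bar x_w)(y-\bar y_w) / \sqrt{\sum w (x-\bar x_w)^2
#' \sum w (y-\bar y_w)^2}} with weighted means; invariant to rescaling the
#' weights and to positive affine transforms of `x` and `y`. Undefined
#' (returned as `NA` with a warning) with fewer than 3 pairs or zero
#' weighted variance -- never coerced to 0.
#'
#' @param x,y numeric vectors of equal length.
#' @param w positive weights; `NULL` for uniform.
#' @return A single correlation in \[-1, 1\], or `NA`.
#' @examples
#' weighted_pearson(1:5, c(2, 4, 5, 4, 5), w = rep(1, 5))
#' @export
weighted_pearson <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(x) == length(y), length(w) == length(x))
  keep <- !is.na(x) & !is.na(y) & !is.na(w)
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (length(x) < 3L) {
    warn("fewer than 3 complete pairs: correlation undefined")
    return(NA_real_)
  }
  if (any(w <= 0)) abort("weights must be positive")
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    warn("zero weighted variance: correlation undefined")
    return(NA_real_)
  }
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Correlation strength label
#'
#' Bands on the magnitude of r: negligible below 0.10, weak 0.10-0.39,
#' moderate 0.40-0.69, strong 0.70-0.89, very strong 0.90-1.00. Band edges
#' belong to the higher band.
#'
#' @param r correlation(s).
#' @return Character vector of labels (`NA` in, `NA` out).
#' @examples
#' strength_label(c(0.6, -0.32, 0.05))
#' @export
strength_label <- function(r) {
  out <- rep(NA_character_, length(r))
  a <- abs(r)
  out[!is.na(a) & a < 0.10] <- "negligible"
  out[!is.na(a) & a >= 0.10 & a < 0.40] <- "weak"
  out[!is.na(a) & a >= 0.40 & a < 0.70] <- "moderate"
  out[!is.na(a) & a >= 0.70 & a < 0.90] <- "strong"
  out[!is.na(a) & a >= 0.90] <- "very strong"
  out
}

#' Percent agreement and Cohen's kappa
#'
#' Unweighted kappa \eqn{(p_o - p_e)/(1 - p_e)}, with expected agreement
#' \eqn{p_e} from the product of the two marginal label distributions over
#' the union of observed categories. When the margins put all mass on one
#' shared category (\eqn{p_e = 1}) kappa is undefined and returned as `NA`.
#'
#' @param l0,l1 label vectors (e.g. tertiles at the two waves).
#' @return A list with `pct_agreement`, `kappa` and `n`.
#' @examples
#' agreement_kappa(c(1, 1, 2, 2), c(2, 2, 1, 1))
#' @export
agreement_kappa <- function(l0, l1) {
  keep <- !is.na(l0) & !is.na(l1)
  l0 <- l0[keep]; l1 <- l1[keep]
  n <- length(l0)
  if (n < 1L) {
    warn("no complete label pairs: agreement undefined")
    return(list(pct_agreement = NA_real_, kappa = NA_real_, n = 0L))
  }
  cats <- sort(unique(c(l0, l1)))
  p_o <- mean(l0 == l1)
  m0 <- vapply(cats, function(k) mean(l0 == k), numeric(1))
  m1 <- vapply(cats, function(k) mean(l1 == k), numeric(1))
  p_e <- sum(m0 * m1)
  kappa <- if (1 - p_e <= .Machine$double.eps) {
    warn("degenerate margins (p_e = 1): kappa undefined")
    NA_real_
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  list(pct_agreement = p_o, kappa = kappa, n = n)
}

#' Paired absolute and net differences
#'
#' Mean of the absolute score change |s1 - s0| (magnitude of change) and of
#' the signed change s1 - s0 (net drift), overall or within a grouping such
#' as tier or major region.
#'
#' @param paired output of [paired_scores()].
#' @param by optional grouping column name (`"tier"` or `"major_region"`).
#' @return A tibble per measure (and group): `n`, `mean_abs_diff`,
#'   `mean_net_diff`.
#' @export
paired_differences <- function(paired, by = NULL) {
  g <- c("measure", by)
  dplyr::summarise(
    dplyr::group_by(paired, dplyr::across(dplyr::all_of(g))),
    n = dplyr::n(),
    mean_abs_diff = mean(abs(.data$score_t1 - .data$score_t0)),
    mean_net_diff = mean(.data$score_t1 - .data$score_t0),
    .groups = "drop")
}

#' Facility-level stability summary
#'
#' Per measure (optionally within tiers): number of pairs, mean absolute and
#' net change, Pearson correlation weighted by the facility sampling weight
#' from the earlier wave of each pair (or the later wave for sensitivity),
#' its strength band, and -- when tertiles are attached -- percent agreement
#' and Cohen's kappa of the tertile classifications.
#'
#' @param paired output of [paired_scores()].
#' @param by optional grouping column name.
#' @param weight_wave `"earlier"` (primary) or `"later"` (sensitivity).
#' @return A tibble with one row per measure (and group).
#' @export
facility_stability <- function(paired, by = NULL,
                               weight_wave = c("earlier", "later")) {
  weight_wave <- match.arg(weight_wave)
  wcol <- if (weight_wave == "earlier") "weight_t0" else "weight_t1"
  has_tert <- all(c("tertile_t0", "tertile_t1") %in% names(paired))
  g <- c("measure", by)
  dplyr::reframe(
    dplyr::group_by(paired, dplyr::across(dplyr::all_of(g))),
    {
      s0 <- .data$score_t0; s1 <- .data$score_t1
      r <- weighted_pearson(s0, s1, .data[[wcol]])
      ak <- if (has_tert) {
        agreement_kappa(.data$tertile_t0, .data$tertile_t1)
      } else {
        list(pct_agreement = NA_real_, kappa = NA_real_)
      }
      tibble::tibble(
        n = length(s0),
        mean_abs_diff = mean(abs(s1 - s0)),
        mean_net_diff = mean(s1 - s0),
        pearson_r = r,
        strength = strength_label(r),
        pct_agreement = ak$pct_agreement,
        kappa = ak$kappa)
    })
}

#' Sensitivity of correlations to the weighting wave
#'
#' Recomputes the facility-level weighted correlation using the later wave's
#' facility weights and reports both values side by side.
#'
#' @param paired output of [paired_scores()].
#' @return A tibble per measure: `n`, `r_earlier`, `r_later`, `r_diff`.
#' @export
sensitivity_weights <- function(paired) {
  a <- facility_stability(paired, weight_wave = "earlier")
  b <- facility_stability(paired, weight_wave = "later")
  tibble::tibble(measure = a$measure, n = a$n, r_earlier = a$pearson_r,
                 r_later = b$pearson_r, r_diff = b$pearson_r - a$pearson_r)
}

#' Regional quality values per pair set and wave
#'
#' Averages quality to the four major regions within the analytic sample of
#' paired facilities: facility-weighted means of facility scores for
#' structural measures and the signal-function measure, and client-weighted
#' means over all observed visits for the direct-observation process
#' measures. One value per major region, pair set, measure and wave side.
#'
#' @param paired output of [paired_scores()].
#' @param visit_scores optional per-visit scores from [score_visits()]; if
#'   supplied, process measures are averaged over visits rather than over
#'   facility means.
#' @return A tibble: `major_region`, `pair_set`, `measure`, `value_t0`,
#'   `value_t1`.
#' @export
regional_scores <- function(paired, visit_scores = NULL) {
  fac_part <- dplyr::summarise(
    dplyr::group_by(paired, .data$major_region, .data$pair_set, .data$measure),
    value_t0 = wmean(.data$score_t0, .data$weight_t0),
    value_t1 = wmean(.data$score_t1, .data$weight_t1),
    .groups = "drop")
  if (is.null(visit_scores)) return(fac_part)

  vs <- visit_scores[!is.na(visit_scores$score), ]
  vs$measure <- ifelse(vs$service == "ANC", "process_anc", "process_child")
  meta <- dplyr::distinct(paired[, c("facility_id", "pair_set", "wave_t0",
                                     "wave_t1", "major_region")])
  join0 <- dplyr::inner_join(vs, meta,
                             by = c("facility_id", "wave" = "wave_t0"))
  join1 <- dplyr::inner_join(vs, meta,
                             by = c("facility_id", "wave" = "wave_t1"))
  v0 <- dplyr::summarise(
    dplyr::group_by(join0, .data$major_region, .data$pair_set, .data$measure),
    value_t0 = wmean(.data$score, .data$client_weight), .groups = "drop")
  v1 <- dplyr::summarise(
    dplyr::group_by(join1, .data$major_region, .data$pair_set, .data$measure),
    value_t1 = wmean(.data$score, .data$client_weight), .groups = "drop")
  vis_part <- dplyr::inner_join(v0, v1,
                                by = c("major_region", "pair_set", "measure"))
  dplyr::bind_rows(
    fac_part[!fac_part$measure %in% c("process_anc", "process_child"), ],
    vis_part)
}

#' Regional stability summary
#'
#' Correlates the region-level quality values across the two waves, pooling
#' the major-region by pair-set points for each measure (up to 4 regions
#' times 4 pair sets). Correlations on fewer than 3 points are flagged
#' undefined.
#'
#' @inheritParams regional_scores
#' @return A tibble per measure: `n` (region-by-pair-set points),
#'   `pearson_r`, `strength`, `mean_abs_diff`, `mean_net_diff`.
#' @export
regional_stability <- function(paired, visit_scores = NULL) {
  rs <- regional_scores(paired, visit_scores)
  dplyr::reframe(
    dplyr::group_by(rs, .data$measure),
    {
      v0 <- .data$value_t0; v1 <- .data$value_t1
      r <- weighted_pearson(v0, v1)
      tibble::tibble(
        n = length(v0),
        pearson_r = r,
        strength = strength_label(r),
        mean_abs_diff = mean(abs(v1 - v0)),
        mean_net_diff = mean(v1 - v0))
    })
}

#' Full stability analysis of a paired panel
#'
#' Bundles the facility-level, tier-level and regional stability summaries,
#' the paired-difference tables and the weighting sensitivity analysis into
#' one object with [tidy()], [glance()] and [ggplot2::autoplot()] methods.
#'
#' @param pairs output of [pair_assessments()].
#' @param scores long score table.
#' @param tertiles tertile table; computed from `scores` if `NULL`.
#' @param visit_scores optional per-visit scores for regional process
#'   averaging.
#' @return An object of class `qualstab_stability`.
#' @examples
#' sim <- simulate_survey_data(sim_config(), seed = 5)
#' scores <- score_facilities(sim)
#' pairs <- pair_assessments(sim$facilities)
#' fit <- quality_stability(pairs, scores)
#' tidy(fit)
#' @export
quality_stability <- function(pairs, scores, tertiles = NULL,
                              visit_scores = NULL) {
  if (is.null(tertiles)) {
    panel_waves <- dplyr::bind_rows(
      tibble::tibble(facility_id = pairs$facility_id, wave = pairs$wave_t0),
      tibble::tibble(facility_id = pairs$facility_id, wave = pairs$wave_t1))
    panel_scores <- dplyr::semi_join(scores, panel_waves,
                                     by = c("facility_id", "wave"))
    tertiles <- classify_tertiles(panel_scores)
  }
  paired <- paired_scores(pairs, scores, tertiles)
  structure(
    list(paired = paired,
         facility = facility_stability(paired),
         by_tier = facility_stability(paired, by = "tier"),
         regional = regional_stability(paired, visit_scores),
         differences = paired_differences(paired, by = "major_region"),
         sensitivity = sensitivity_weights(paired)),
    class = "qualstab_stability")
}

#' @export
print.qualstab_stability <- function(x, ...) {
  cat("<qualstab_stability>", nrow(x$paired), "pair-measure records\n\n")
  cat("Facility-level stability:\n")
  print(x$facility, n = Inf)
  invisible(x)
}
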