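# Quality scoring: SARA-style readiness indices, direct-observation process
# scores with ANC follow-up weighting, BEmONC signal-function proportion,
# and equal-width tertile classification.

#' Readiness scores per facility and wave
#'
#' Scores each readiness instrument as the proportion of items present out
#' of items assessed (missing responses are excluded from the denominator;
#' set `missing_as_absent = TRUE` to count them as absent instead). With
#' `aggregation = "domain_mean"` the score is the unweighted mean of domain
#' proportions, the classic SARA index form; the default pools items
#' directly.
#'
#' @param items long item-response table (`facility_id`, `wave`,
#'   `instrument`, `item_id`, `response` in 0/1/NA).
#' @param registry the item registry.
#' @param aggregation `"item_mean"` (default) or `"domain_mean"`.
#' @param missing_as_absent treat missing responses as absent (0) rather
#'   than not assessed.
#' @return A tibble: `facility_id`, `wave`, `measure`, `value`,
#'   `n_items_assessed`. Facilities with no assessed item get `NA`.
#' @examples
#' reg <- item_registry(seed = 1)
#' it <- tibble::tibble(facility_id = "f1", wave = 2015,
#'                      instrument = "readiness_anc",
#'                      item_id = reg$item_id[reg$instrument == "readiness_anc"],
#'                      response = c(1, 1, 1, 0, 0, 0, 0, 0, 0))
#' score_readiness(it, reg)
#' @export
score_readiness <- function(items, registry,
                            aggregation = c("item_mean", "domain_mean"),
                            missing_as_absent = FALSE) {
  aggregation <- match.arg(aggregation)
  d <- items[items$instrument %in% c("readiness_general", "readiness_anc",
                                     "readiness_obstetric", "readiness_child"), ]
  d <- dplyr::left_join(d, registry[, c("instrument", "item_id", "domain")],
                        by = c("instrument", "item_id"))
  if (missing_as_absent) d$response[is.na(d$response)] <- 0L
  if (aggregation == "item_mean") {
    out <- dplyr::summarise(
      dplyr::group_by(d, .data$facility_id, .data$wave, .data$instrument),
      value = if (sum(!is.na(.data$response)) == 0L) NA_real_ else
        mean(.data$response, na.rm = TRUE),
      n_items_assessed = sum(!is.na(.data$response)),
      .groups = "drop")
  } else {
    dom <- dplyr::summarise(
      dplyr::group_by(d, .data$facility_id, .data$wave, .data$instrument,
                      .data$domain),
      dv = if (sum(!is.na(.data$response)) == 0L) NA_real_ else
        mean(.data$response, na.rm = TRUE),
      n = sum(!is.na(.data$response)),
      .groups = "drop_last")
    out <- dplyr::summarise(
      dom,
      value = if (all(is.na(.data$dv))) NA_real_ else
        mean(.data$dv, na.rm = TRUE),
      n_items_assessed = sum(.data$n),
      .groups = "drop")
  }
  out$measure <- instrument_measure_map[out$instrument]
  out[, c("facility_id", "wave", "measure", "value", "n_items_assessed")]
}

#' Readiness domain scores
#'
#' Proportion of items present per readiness domain (basic amenities,
#' equipment, infection prevention, diagnostics, medications, ...), used for
#' domain-level stability comparisons.
#'
#' @inheritParams score_readiness
#' @return A tibble: `facility_id`, `wave`, `measure`, `domain`, `value`,
#'   `n_items_assessed`.
#' @export
score_readiness_domains <- function(items, registry) {
  d <- items[items$instrument %in% c("readiness_general", "readiness_anc",
                                     "readiness_obstetric", "readiness_child"), ]
  d <- dplyr::left_join(d, registry[, c("instrument", "item_id", "domain")],
                        by = c("instrument", "item_id"))
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$facility_id, .data$wave, .data$instrument,
                    .data$domain),
    value = if (sum(!is.na(.data$response)) == 0L) NA_real_ else
      mean(.data$response, na.rm = TRUE),
    n_items_assessed = sum(!is.na(.data$response)),
    .groups = "drop")
  out$measure <- instrument_measure_map[out$instrument]
  out[, c("facility_id", "wave", "measure", "domain", "value",
          "n_items_assessed")]
}

#' BEmONC signal-function score
#'
#' Proportion of the 7 Basic Emergency Obstetric and Newborn Care signal
#' functions reported as performed in the prior three months. The
#' denominator is fixed at 7; a function with a missing report counts as not
#' performed, and the score is missing only when all 7 reports are missing.
#'
#' @param items long item-response table containing the `bemonc` instrument.
#' @return A tibble: `facility_id`, `wave`, `measure`
#'   (`process_obstetric_signal`), `value`, `n_items_assessed`.
#' @export
score_bemonc <- function(items) {
  d <- items[items$instrument == "bemonc", ]
  dplyr::summarise(
    dplyr::group_by(d, .data$facility_id, .data$wave),
    measure = "process_obstetric_signal",
    value = if (all(is.na(.data$response))) NA_real_ else
      sum(.data$response, na.rm = TRUE) / 7,
    n_items_assessed = sum(!is.na(.data$response)),
    .groups = "drop")
}

#' Score directly observed visits
#'
#' Scores each observed consultation as the proportion of recommended
#' actions completed out of actions assessed. Actions in ANC follow-up
#' visits are weighted 1/3, 2/3 or 1 according to the registry's follow-up
#' weights (reflecting how many of ANC visits 2-4 recommend the action);
#' first ANC visits and child visits use weight 1 throughout. Visits with no
#' assessed action get a missing score and a warning.
#'
#' @param visits long visit-action table from [simulate_visits()] or
#'   equivalent (`visit_id`, `facility_id`, `wave`, `service`,
#'   `visit_order`, `client_weight`, `action_id`, `response`).
#' @param registry the item registry.
#' @return One row per visit: `visit_id`, `facility_id`, `wave`, `service`,
#'   `visit_order`, `client_weight`, `score`, `n_actions_assessed`.
#' @export
score_visits <- function(visits, registry) {
  if (nrow(visits) == 0L) {
    return(tibble::tibble(visit_id = character(), facility_id = character(),
                          wave = integer(), service = character(),
                          visit_order = character(), client_weight = double(),
                          score = double(), n_actions_assessed = integer()))
  }
  reg <- registry[registry$instrument %in% c("process_anc", "process_child"),
                  c("item_id", "followup_weight")]
  d <- dplyr::left_join(visits, reg, by = c("action_id" = "item_id"))
  if (anyNA(d$followup_weight)) {
    abort("visit actions not found in registry")
  }
  followup <- d$service == "ANC" & !is.na(d$visit_order) &
    d$visit_order != "first"
  d$w <- ifelse(followup, d$followup_weight, 1)
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$visit_id, .data$facility_id, .data$wave,
                    .data$service, .data$visit_order, .data$client_weight),
    score = {
      ok <- !is.na(.data$response)
      if (!any(ok)) NA_real_ else
        sum(.data$w[ok] * .data$response[ok]) / sum(.data$w[ok])
    },
    n_actions_assessed = sum(!is.na(.data$response)),
    .groups = "drop")
  if (any(is.na(out$score))) {
    warn(sprintf("%d visit(s) with no assessed action excluded from scores",
                 sum(is.na(out$score))))
  }
  out
}

#' Aggregate visit scores to facility process scores
#'
#' Facilities are assigned the client-weight-weighted average of their
#' observed visits' scores for each service. Facility-waves with no
#' scoreable visit are omitted (the measure is missing there).
#'
#' @param visit_scores output of [score_visits()].
#' @return A tibble: `facility_id`, `wave`, `measure` (`process_anc` or
#'   `process_child`), `value`, `n_visits`.
#' @export
aggregate_visit_scores <- function(visit_scores) {
  d <- visit_scores[!is.na(visit_scores$score), ]
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$facility_id, .data$wave, .data$service),
    value = sum(.data$client_weight * .data$score) / sum(.data$client_weight),
    n_visits = dplyr::n(),
    .groups = "drop")
  out$measure <- ifelse(out$service == "ANC", "process_anc", "process_child")
  out[, c("facility_id", "wave", "measure", "value", "n_visits")]
}

#' All quality scores for a simulated or supplied dataset
#'
#' Runs readiness, BEmONC and visit-process scoring and binds the results
#' into one long score table, the unit of all downstream stability and
#' coverage analysis.
#'
#' @param sim a `qualstab_sim` object, or a list with `readiness_items`,
#'   `visits` and `registry` elements.
#' @param aggregation readiness aggregation rule, see [score_readiness()].
#' @return A tibble: `facility_id`, `wave`, `measure`, `value`,
#'   `n_items_assessed`, `n_visits`.
#' @examples
#' sim <- simulate_survey_data(sim_config(), seed = 3)
#' scores <- score_facilities(sim)
#' dplyr::count(scores, measure)
#' @export
score_facilities <- function(sim, aggregation = c("item_mean", "domain_mean")) {
  aggregation <- match.arg(aggregation)
  readiness <- score_readiness(sim$readiness_items, sim$registry, aggregation)
  bemonc <- score_bemonc(sim$readiness_items)
  process <- aggregate_visit_scores(score_visits(sim$visits, sim$registry))
  out <- dplyr::bind_rows(
    dplyr::mutate(readiness, n_visits = NA_integer_),
    dplyr::mutate(bemonc, n_visits = NA_integer_),
    dplyr::mutate(process, n_items_assessed = NA_integer_))
  dplyr::arrange(out, .data$facility_id, .data$wave, .data$measure)
}

#' Classify facilities into tertiles of the observed score range
#'
#' For each measure and wave year, the observed \[min, max\] range is split
#' into three equal-width intervals: tertile 1 is the lowest third,
#' boundaries belong to the lower interval, and the maximum falls in
#' tertile 3. If all scores in a cell are identical (zero-width range) every
#' facility is assigned the middle tertile with a warning.
#'
#' @param scores long score table (from [score_facilities()]).
#' @return A tibble: `facility_id`, `wave`, `measure`, `tertile` in 1:3.
#' @examples
#' s <- tibble::tibble(facility_id = c("a", "b", "c"), wave = 2015,
#'                     measure = "readiness_general", value = c(0, 0.5, 1))
#' classify_tertiles(s)
#' @export
classify_tertiles <- function(scores) {
  d <- scores[!is.na(scores$value), ]
  out <- dplyr::mutate(
    dplyr::group_by(d, .data$measure, .data$wave),
    tertile = {
      lo <- min(.data$value); hi <- max(.data$value)
      if (hi - lo <= 0) {
        warn(sprintf(
          "zero-width score range for %s at wave %s: all facilities tertile 2",
          .data$measure[1], .data$wave[1]))
        rep(2L, dplyr::n())
      } else {
        b <- lo + (hi - lo) * c(1, 2) / 3
        1L + (.data$value > b[1]) + (.data$value > b[2])
      }
    })
  out <- dplyr::ungroup(out)
  out[, c("facility_id", "wave", "measure", "tertile")]
}
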