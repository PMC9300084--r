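# Pipeline orchestration and schema-validated tabular I/O.

table_schemas <- function() {
  list(
    facilities = list(
      required = c("facility_id", "wave", "tier", "authority", "region",
                   "major_region", "urbanicity", "facility_weight"),
      categorical = list(tier = TIERS, authority = c("public", "private"),
                         urbanicity = c("urban", "rural"),
                         major_region = c("West", "Centre", "North", "South")),
      positive = "facility_weight",
      unique_key = c("facility_id", "wave")),
    readiness_items = list(
      required = c("facility_id", "wave", "instrument", "item_id", "response"),
      categorical = list(instrument = c("readiness_general", "readiness_anc",
                                        "readiness_obstetric",
                                        "readiness_child", "bemonc")),
      domain01 = "response"),
    visits = list(
      required = c("visit_id", "facility_id", "wave", "service",
                   "visit_order", "client_weight", "action_id", "response"),
      categorical = list(service = c("ANC", "child")),
      positive = "client_weight",
      domain01 = "response"),
    households = list(
      required = c("unit_id", "unit_type", "major_region", "survey_year",
                   "anc_sources", "anc_visits", "delivery_source",
                   "child_source", "survey_weight"),
      categorical = list(unit_type = c("woman_live_birth_2y",
                                       "child_under5_symptomatic_2w"),
                         major_region = c("West", "Centre", "North", "South")),
      positive = "survey_weight")
  )
}

#' Validate a pipeline table against its schema
#'
#' Checks column presence, categorical domains, weight positivity, 0/1
#' response domains and key uniqueness, returning row-level diagnostics.
#'
#' @param data a data frame, or a path to a CSV file.
#' @param schema_name one of `"facilities"`, `"readiness_items"`,
#'   `"visits"`, `"households"`.
#' @return A tibble of diagnostics (zero rows when the table passes), with
#'   attribute `pass`.
#' @examples
#' sim <- simulate_survey_data(sim_config(), seed = 2)
#' v <- validate_table(sim$facilities, "facilities")
#' attr(v, "pass")
#' @export
validate_table <- function(data, schema_name) {
  schemas <- table_schemas()
  if (!schema_name %in% names(schemas)) {
    abort(sprintf("unknown schema `%s`", schema_name))
  }
  sch <- schemas[[schema_name]]
  if (is.character(data)) {
    if (!file.exists(data)) abort(sprintf("file not found: %s", data))
    data <- readr::read_csv(data, show_col_types = FALSE, progress = FALSE)
  }
  diags <- list()
  note <- function(row, column, problem) {
    diags[[length(diags) + 1L]] <<- tibble::tibble(
      row = as.integer(row), column = column, problem = problem)
  }
  missing_cols <- setdiff(sch$required, names(data))
  if (length(missing_cols) > 0) {
    note(NA, missing_cols, "missing column")
  } else {
    for (col in names(sch$categorical %||% list())) {
      bad <- which(!is.na(data[[col]]) &
                     !data[[col]] %in% sch$categorical[[col]])
      for (r in bad) note(r, col, paste0("invalid code: ", data[[col]][r]))
    }
    for (col in sch$positive %||% character()) {
      bad <- which(is.na(data[[col]]) | data[[col]] <= 0)
      for (r in bad) note(r, col, "weight must be positive")
    }
    for (col in sch$domain01 %||% character()) {
      bad <- which(!is.na(data[[col]]) & !data[[col]] %in% c(0, 1))
      for (r in bad) note(r, col, "response must be 0, 1 or missing")
    }
    if (!is.null(sch$unique_key)) {
      dup <- which(duplicated(data[, sch$unique_key]))
      for (r in dup) {
        note(r, paste(sch$unique_key, collapse = "+"),
             paste0("duplicate key: ",
                    paste(unlist(data[r, sch$unique_key]), collapse = " @ ")))
      }
    }
  }
  out <- if (length(diags) == 0) {
    tibble::tibble(row = integer(), column = character(),
                   problem = character())
  } else {
    dplyr::bind_rows(diags)
  }
  attr(out, "pass") <- nrow(out) == 0L
  out
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a paired SPA/DHS dataset, score facilities, pair
#' assessments, run the stability analysis and the adjusted-coverage
#' comparison, and optionally write every result table to CSV together with
#' a manifest recording the seed and row counts.
#'
#' @param config a [sim_config()] object.
#' @param seed master integer seed.
#' @param sim an existing `qualstab_sim` dataset; simulated from `config`
#'   and `seed` when `NULL`.
#' @param readiness_aggregation readiness aggregation rule.
#' @param output_dir if non-`NULL`, directory where CSV outputs are written.
#' @return A list of class `qualstab_pipeline`: the input tables, `scores`,
#'   `tertiles`, `pairs`, `stability` (a `qualstab_stability`),
#'   `coverage_estimates`, `coverage_differences`, `coverage_summary` and
#'   `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(), seed = 11)
#' res$stability$facility
#' }
#' @export
run_pipeline <- function(config = sim_config(), seed, sim = NULL,
                         readiness_aggregation = c("item_mean", "domain_mean"),
                         output_dir = NULL) {
  readiness_aggregation <- match.arg(readiness_aggregation)
  if (is.null(sim)) sim <- simulate_survey_data(config, seed)
  for (nm in c("facilities", "readiness_items", "visits", "households")) {
    v <- validate_table(sim[[nm]], nm)
    if (!attr(v, "pass")) {
      abort(sprintf("input table `%s` failed validation (%d problem(s)); first: %s %s",
                    nm, nrow(v), v$column[1], v$problem[1]))
    }
  }
  scores <- score_facilities(sim, aggregation = readiness_aggregation)
  pairs <- pair_assessments(sim$facilities)
  visit_scores <- score_visits(sim$visits, sim$registry)
  stability <- quality_stability(pairs, scores, visit_scores = visit_scores)
  estimates <- estimate_adjusted_coverage(sim$households, pairs, scores)
  differences <- compare_adjusted_coverage(estimates)
  res <- list(
    facilities = sim$facilities, readiness_items = sim$readiness_items,
    visits = sim$visits, households = sim$households,
    scores = scores,
    tertiles = classify_tertiles(
      dplyr::semi_join(scores, dplyr::bind_rows(
        tibble::tibble(facility_id = pairs$facility_id, wave = pairs$wave_t0),
        tibble::tibble(facility_id = pairs$facility_id, wave = pairs$wave_t1)),
        by = c("facility_id", "wave"))),
    pairs = pairs,
    stability = stability,
    coverage_estimates = estimates,
    coverage_differences = differences,
    coverage_summary = summarise_coverage_differences(differences),
    seed = sim$seed
  )
  res$manifest <- pipeline_manifest(res)
  class(res) <- "qualstab_pipeline"
  if (!is.null(output_dir)) write_pipeline(res, output_dir)
  res
}

pipeline_tables <- c("facilities", "readiness_items", "visits", "households",
                     "scores", "tertiles", "pairs", "coverage_estimates",
                     "coverage_differences", "coverage_summary")

pipeline_manifest <- function(res) {
  tibble::tibble(
    table = c(pipeline_tables, "stability_facility", "stability_region"),
    rows = c(vapply(pipeline_tables, function(t) nrow(res[[t]]), integer(1)),
             nrow(res$stability$facility), nrow(res$stability$regional)),
    seed = res$seed)
}

#' Write pipeline outputs to CSV
#'
#' Writes every result table, the stability summaries and a manifest
#' (table, row count, seed) into `dir`. Inputs are never mutated and a
#' rerun with the same seed reproduces every file byte for byte; doubles
#' are written with 15 significant digits so that a write-read-write cycle
#' is also byte-stable.
#'
#' @param res a `qualstab_pipeline` object.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(res, dir) {
  stopifnot(inherits(res, "qualstab_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in pipeline_tables) {
    write_csv_stable(res[[t]], file.path(dir, paste0(t, ".csv")))
  }
  write_csv_stable(res$stability$facility,
                   file.path(dir, "stability_facility.csv"))
  write_csv_stable(res$stability$by_tier,
                   file.path(dir, "stability_by_tier.csv"))
  write_csv_stable(res$stability$regional,
                   file.path(dir, "stability_region.csv"))
  write_csv_stable(res$stability$differences,
                   file.path(dir, "differences.csv"))
  write_csv_stable(res$stability$sensitivity,
                   file.path(dir, "sensitivity_weights.csv"))
  write_csv_stable(res$manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

write_csv_stable <- function(df, path) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.15g", col)
      out[is.na(col)] <- NA_character_
      out
    } else {
      col
    }
  })
  readr::write_csv(df, path, progress = FALSE)
}

#' @export
print.qualstab_pipeline <- function(x, ...) {
  cat("<qualstab_pipeline> seed", x$seed, "\n")
  print(x$manifest, n = Inf)
  invisible(x)
}
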