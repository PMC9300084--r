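#' Instrument and item registry
#'
#' Builds the registry of items behind each quality instrument: SARA-style
#' readiness indices for general services (48 items) and for antenatal care,
#' basic obstetric care and child care (9, 19 and 18 items), the
#' direct-observation adherence checklists (27 ANC actions, 25 child actions)
#' and the 7 BEmONC signal functions. Item identities are abstract: the
#' registry carries instrument membership, a domain label, a per-item
#' difficulty offset used by the synthetic-data generator, and the follow-up
#' weight attached to ANC actions (1/3, 2/3 or 1 according to the visit at
#' which the action is first recommended; all other items weigh 1).
#'
#' Difficulties are drawn once (from a zero-mean normal) and fixed across
#' waves, so that items as well as facilities induce realistic score
#' dispersion.
#'
#' @param difficulty_sd standard deviation of item difficulty offsets on the
#'   logit scale.
#' @param seed integer seed for the difficulty draws; the registry is fully
#'   reproducible given the seed.
#' @return A tibble with columns `instrument`, `item_id`, `domain`,
#'   `difficulty` and `followup_weight`.
#' @examples
#' reg <- item_registry(seed = 1)
#' dplyr::count(reg, instrument)
#' @export
item_registry <- function(difficulty_sd = 0.8, seed = 1L) {
  spec <- list(
    readiness_general = c(basic_amenities = 10, basic_equipment = 10,
                          infection_prevention = 10, diagnostics = 8,
                          medications = 10),
    readiness_anc = c(staff_guidelines = 2, basic_equipment = 1,
                      diagnostics = 2, medications = 4),
    readiness_obstetric = c(staff_guidelines = 4, basic_equipment = 6,
                            medications = 9),
    readiness_child = c(staff_guidelines = 4, basic_equipment = 4,
                        diagnostics = 4, medications = 6),
    process_anc = c(history = 7, examination = 7, counselling = 7, tests = 6),
    process_child = c(assessment = 10, examination = 8, counselling = 7),
    bemonc = c(signal_functions = 7)
  )
  rows <- purrr::imap(spec, function(domains, instr) {
    tibble::tibble(
      instrument = instr,
      item_id = sprintf("%s_%02d", instr, seq_len(sum(domains))),
      domain = rep(names(domains), domains)
    )
  })
  reg <- dplyr::bind_rows(rows)
  reg$followup_weight <- 1
  anc <- reg$instrument == "process_anc"
  # one third of ANC actions recommended at every follow-up visit (weight 1),
  # one third from visit 3 on (2/3), one third only at visit 4 (1/3)
  reg$followup_weight[anc] <- rep(c(1, 2 / 3, 1 / 3), length.out = sum(anc))
  with_substream(seed, "item_difficulty", {
    reg$difficulty <- rnorm(nrow(reg), 0, difficulty_sd)
  })
  reg
}

# Instrument sizes used for validation.
instrument_sizes <- function() {
  c(readiness_general = 48L, readiness_anc = 9L, readiness_obstetric = 19L,
    readiness_child = 18L, process_anc = 27L, process_child = 25L,
    bemonc = 7L)
}

check_registry <- function(registry) {
  sizes <- instrument_sizes()
  counts <- table(registry$instrument)
  for (instr in names(sizes)) {
    if (is.na(counts[instr]) || counts[instr] != sizes[instr]) {
      abort(sprintf("registry instrument `%s` must have %d items", instr,
                    sizes[instr]))
    }
  }
  ok <- registry$followup_weight %in% c(1 / 3, 2 / 3, 1)
  if (!all(ok)) abort("followup_weight must be one of 1/3, 2/3, 1")
  invisible(registry)
}
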