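# Independent brute-force oracles used to cross-check the vectorised
# implementations, plus small fixture builders.

# Readiness score by explicit loop: items present / items assessed.
oracle_readiness <- function(responses) {
  num <- 0L; den <- 0L
  for (r in responses) {
    if (!is.na(r)) {
      den <- den + 1L
      if (r == 1L) num <- num + 1L
    }
  }
  if (den == 0L) NA_real_ else num / den
}

# Visit process score by explicit loop with per-action weights.
oracle_visit_score <- function(responses, weights) {
  num <- 0; den <- 0
  for (i in seq_along(responses)) {
    if (!is.na(responses[i])) {
      den <- den + weights[i]
      num <- num + weights[i] * responses[i]
    }
  }
  if (den == 0) NA_real_ else num / den
}

# BEmONC: performed / 7, missing only if all reports missing.
oracle_bemonc <- function(responses) {
  if (all(is.na(responses))) return(NA_real_)
  sum(responses[!is.na(responses)]) / 7
}

# Textbook weighted Pearson, written independently of the package's form.
oracle_weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cxy <- 0; cxx <- 0; cyy <- 0
  for (i in seq_along(x)) {
    cxy <- cxy + w[i] * (x[i] - mx) * (y[i] - my)
    cxx <- cxx + w[i] * (x[i] - mx)^2
    cyy <- cyy + w[i] * (y[i] - my)^2
  }
  cxy / sqrt(cxx * cyy)
}

# Cohen's kappa from the contingency table, by loops.
oracle_kappa <- function(l0, l1) {
  cats <- sort(unique(c(l0, l1)))
  n <- length(l0)
  p_o <- sum(l0 == l1) / n
  p_e <- 0
  for (k in cats) {
    p_e <- p_e + (sum(l0 == k) / n) * (sum(l1 == k) / n)
  }
  (p_o - p_e) / (1 - p_e)
}

# A small, fast generator configuration for pipeline-level tests; any
# sim_config() argument can be overridden.
small_config <- function(...) {
  args <- list(
    n_regions = 4,
    facilities_per_stratum = c(hospital = 2, health_centre = 4,
                               health_post = 10),
    households_per_region = c(woman = 60, child = 60))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Readiness-only configuration (no visits, no household use) for latent
# parameter studies; hospitals and health centres only so every sampled
# facility is paired.
panel_config <- function(rho, n_hosp = 10, n_hc = 12, ...) {
  sim_config(
    facilities_per_stratum = c(hospital = n_hosp, health_centre = n_hc,
                               health_post = 0),
    rho = rho,
    service_offered_prob = c(ANC = 0, child = 0),
    households_per_region = c(woman = 1, child = 1),
    ...)
}

# Build an item-response table for one facility-wave from a response vector.
items_for <- function(registry, instrument, responses, facility_id = "f1",
                      wave = 2015L) {
  ids <- registry$item_id[registry$instrument == instrument]
  stopifnot(length(ids) == length(responses))
  tibble::tibble(facility_id = facility_id, wave = wave,
                 instrument = instrument, item_id = ids,
                 response = as.integer(responses))
}
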