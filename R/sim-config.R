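#' Synthetic survey configuration
#'
#' Assembles and validates the configuration of the synthetic-data generator.
#' The defaults emulate the design of the Senegal continuous SPA facility
#' survey paired with the continuous DHS household survey: 14 administrative
#' regions grouped into 4 major regions (West = 2 regions, Centre = 4,
#' North = 3, South = 5); stratified facility sampling with fractions 0.5 for
#' hospitals and health centres and 0.2 for health posts; hospitals and
#' health centres resampled with certainty two years later and health posts
#' with probability 0.3; small per-facility visit samples (median about five
#' observed child consultations and three to four ANC consultations); and
#' household facility-source choice concentrated in health posts.
#'
#' @param n_regions number of regions; mapped to the 4 major regions by the
#'   2/4/3/5 partition (scaled if `n_regions` differs from 14).
#' @param facilities_per_stratum named count of frame facilities per tier,
#'   per region and per pair-set.
#' @param sampling_fraction named sampling fraction per tier, in (0, 1].
#' @param resample_prob per-tier probability that a wave-t facility is
#'   assessed again at wave t+2.
#' @param resample_third_wave if `TRUE`, resampled facilities may be assessed
#'   a third time (two years after the second wave) with the same per-tier
#'   probability, so a facility can contribute two pairs.
#' @param rho latent test-retest correlation, a scalar or named per measure;
#'   each value in \[-1, 1\].
#' @param mu_tier,sigma_tier location and scale of latent quality per tier on
#'   the logit scale.
#' @param private_share proportion of facilities under private management.
#' @param urban_share per-tier probability that a facility is urban.
#' @param item_difficulty_sd spread of item difficulty offsets (logit scale).
#' @param item_missing_prob probability an item response is not assessed.
#' @param deterministic_items if `TRUE`, item responses are deterministic
#'   thresholds of the latent propensity rather than Bernoulli draws, and no
#'   responses are missing. With `rho = 1` this makes the two waves of each
#'   facility identical.
#' @param service_offered_prob per-service probability that a facility has
#'   observable visits at a wave.
#' @param visit_rate per-service Poisson rate; the number of observed visits
#'   per facility-service is 1 + Poisson(rate).
#' @param visit_count_fixed optional degenerate visit counts per service
#'   (`NA` keeps the Poisson draw; 0 suppresses the service entirely).
#' @param visit_noise_sd between-visit noise on the logit scale.
#' @param action_missing_prob probability an action is not assessed.
#' @param pair_sets list of 2-vectors of wave years two years apart.
#' @param household_years DHS survey years to simulate.
#' @param households_per_region named counts of in-need women and children
#'   per major region and survey year.
#' @param source_probs per-service multinomial over reported sources (must
#'   sum to 1); see [default_source_probs()].
#' @param anc4_fraction probability, by ANC source type, that an ANC user
#'   reaches at least 4 visits.
#' @param multi_source_prob probability an ANC user reports an additional,
#'   lower-ranked source alongside her main one.
#' @return A validated list of class `qualstab_config`.
#' @examples
#' cfg <- sim_config()
#' cfg$sampling_fraction
#' @export
sim_config <- function(n_regions = 14,
                       facilities_per_stratum = c(hospital = 4,
                                                  health_centre = 6,
                                                  health_post = 40),
                       sampling_fraction = c(hospital = 0.5,
                                             health_centre = 0.5,
                                             health_post = 0.2),
                       resample_prob = c(hospital = 1,
                                         health_centre = 1,
                                         health_post = 0.3),
                       resample_third_wave = FALSE,
                       rho = 0.6,
                       mu_tier = c(hospital = 1.0, health_centre = 0.4,
                                   health_post = -0.3),
                       sigma_tier = c(hospital = 0.8, health_centre = 0.8,
                                      health_post = 0.9),
                       private_share = 0.2,
                       urban_share = c(hospital = 0.9, health_centre = 0.7,
                                       health_post = 0.35),
                       item_difficulty_sd = 0.8,
                       item_missing_prob = 0.02,
                       deterministic_items = FALSE,
                       service_offered_prob = c(ANC = 0.6, child = 0.9),
                       visit_rate = c(ANC = 2.8, child = 4.5),
                       visit_count_fixed = c(ANC = NA, child = NA),
                       visit_noise_sd = 0.7,
                       action_missing_prob = 0.05,
                       pair_sets = list(c(2013, 2015), c(2014, 2016),
                                        c(2015, 2017), c(2016, 2018)),
                       household_years = 2015:2019,
                       households_per_region = c(woman = 200, child = 200),
                       source_probs = default_source_probs(),
                       anc4_fraction = c(public_health_post = 0.52,
                                         public_health_centre = 0.58,
                                         public_hospital = 0.62,
                                         private = 0.58),
                       multi_source_prob = 0.10) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    facilities_per_stratum = named_over(facilities_per_stratum, TIERS,
                                        "facilities_per_stratum"),
    sampling_fraction = named_over(sampling_fraction, TIERS,
                                   "sampling_fraction"),
    resample_prob = named_over(resample_prob, TIERS, "resample_prob"),
    resample_third_wave = isTRUE(resample_third_wave),
    rho = named_over(rho, MEASURES, "rho"),
    mu_tier = named_over(mu_tier, TIERS, "mu_tier"),
    sigma_tier = named_over(sigma_tier, TIERS, "sigma_tier"),
    private_share = private_share,
    urban_share = named_over(urban_share, TIERS, "urban_share"),
    item_difficulty_sd = item_difficulty_sd,
    item_missing_prob = item_missing_prob,
    deterministic_items = isTRUE(deterministic_items),
    service_offered_prob = named_over(service_offered_prob, c("ANC", "child"),
                                      "service_offered_prob"),
    visit_rate = named_over(visit_rate, c("ANC", "child"), "visit_rate"),
    visit_count_fixed = named_over(visit_count_fixed, c("ANC", "child"),
                                   "visit_count_fixed"),
    visit_noise_sd = visit_noise_sd,
    action_missing_prob = action_missing_prob,
    pair_sets = pair_sets,
    household_years = as.integer(household_years),
    households_per_region = named_over(households_per_region,
                                       c("woman", "child"),
                                       "households_per_region"),
    source_probs = source_probs,
    anc4_fraction = named_over(anc4_fraction, SOURCE_HIERARCHY,
                               "anc4_fraction"),
    multi_source_prob = multi_source_prob
  )
  class(cfg) <- "qualstab_config"
  validate_config(cfg)
}

#' Default household source-choice probabilities
#'
#' Per-service multinomial probabilities over reported care sources for an
#' in-need individual. The defaults place most facility use in public health
#' posts (about 71% of ANC 1 users, 56% of deliveries and 80% of sick-child
#' visits) and give overall contact coverage near 94% for ANC 1, 74% for
#' facility delivery and 36% for sick-child care; use of health huts or
#' unclassifiable facilities counts as not receiving services.
#'
#' @return A named list with elements `ANC`, `delivery`, `child`, each a
#'   probability vector over the six source categories.
#' @export
default_source_probs <- function() {
  list(
    ANC = c(public_hospital = 0.08, public_health_centre = 0.12,
            public_health_post = 0.67, private = 0.07,
            health_hut_or_unknown = 0.02, none = 0.04),
    delivery = c(public_hospital = 0.10, public_health_centre = 0.155,
                 public_health_post = 0.42, private = 0.07,
                 health_hut_or_unknown = 0.02, none = 0.235),
    child = c(public_hospital = 0.018, public_health_centre = 0.035,
              public_health_post = 0.29, private = 0.019,
              health_hut_or_unknown = 0.03, none = 0.608)
  )
}

validate_config <- function(cfg) {
  bad_frac <- cfg$sampling_fraction <= 0 | cfg$sampling_fraction > 1
  if (any(bad_frac)) {
    abort(sprintf("sampling_fraction out of (0, 1] for tier(s): %s",
                  paste(TIERS[bad_frac], collapse = ", ")))
  }
  if (any(cfg$resample_prob < 0 | cfg$resample_prob > 1)) {
    abort("resample_prob must lie in [0, 1]")
  }
  if (any(cfg$rho < -1 | cfg$rho > 1)) abort("rho must lie in [-1, 1]")
  if (any(cfg$facilities_per_stratum < 0)) {
    abort("facilities_per_stratum must be non-negative")
  }
  if (all(cfg$facilities_per_stratum == 0)) {
    abort("facilities_per_stratum: all strata are empty")
  }
  if (cfg$n_regions < 4) abort("n_regions must be at least 4")
  for (svc in names(cfg$source_probs)) {
    p <- cfg$source_probs[[svc]]
    if (!setequal(names(p), SOURCE_TYPES)) {
      abort(sprintf("source_probs$%s must be named over: %s", svc,
                    paste(SOURCE_TYPES, collapse = ", ")))
    }
    if (abs(sum(p) - 1) > 1e-9) {
      abort(sprintf("source_probs$%s must sum to 1 (got %.10f)", svc, sum(p)))
    }
    if (any(p < 0)) abort(sprintf("source_probs$%s has negative entries", svc))
  }
  for (ps in cfg$pair_sets) {
    if (length(ps) != 2L || ps[2] - ps[1] != 2) {
      abort("each pair_set must be two wave years exactly 2 years apart")
    }
  }
  cfg
}

# Region labels and their mapping to the 4 major regions. With 14 regions the
# partition is West 2, Centre 4, North 3, South 5; other counts are scaled
# proportionally (each major region keeps at least one region).
region_table <- function(n_regions = 14) {
  shares <- c(West = 2, Centre = 4, North = 3, South = 5) / 14
  counts <- setNames(pmax(1L, round(shares * n_regions)), names(shares))
  while (sum(counts) > n_regions) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n_regions) counts[which.min(counts)] <- counts[which.min(counts)] + 1L
  tibble::tibble(
    region = sprintf("region_%02d", seq_len(n_regions)),
    major_region = rep(names(counts), counts)
  )
}
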