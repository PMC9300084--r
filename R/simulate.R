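# Synthetic SPA/DHS data generator.
#
# Latent model: for each facility and measure, quality on the logit scale is
# bivariate normal across the two waves with mean and scale set by facility
# tier and correlation rho. The persistent component rho * z0 carried from
# wave t0 into wave t1 is the shared facility effect; item and visit
# responses are conditionally independent Bernoulli draws around the latent,
# which attenuates score-level correlation below rho.

instrument_measure_map <- c(
  readiness_general = "readiness_general",
  readiness_anc = "readiness_anc",
  readiness_obstetric = "readiness_obstetric",
  readiness_child = "readiness_child",
  process_anc = "process_anc",
  process_child = "process_child",
  bemonc = "process_obstetric_signal"
)

#' Simulate a paired facility-assessment panel
#'
#' Generates the facility sample for each pair of survey waves two years
#' apart: frame facilities are sampled within region-by-tier strata at the
#' configured sampling fractions, then resampled at the second wave with
#' certainty (hospitals, health centres) or the configured probability
#' (health posts). Health posts not resampled appear only at their first
#' wave and drop out of the paired panel downstream. Facility sampling
#' weights equal the inverse sampling fraction of the tier stratum.
#' Readiness-item and signal-function responses are Bernoulli draws with
#' probability `plogis(theta + item difficulty)` around the facility's
#' latent quality.
#'
#' @param config a [sim_config()] object.
#' @param seed master integer seed; all draws run on named substreams of it.
#' @param registry item registry; defaults to one built from the config.
#' @return A list with tibbles `facilities` (one row per facility-wave),
#'   `readiness_items` (long item responses, including the `bemonc`
#'   instrument), `latent` (facility-wave-measure latent values) and the
#'   `registry` used.
#' @examples
#' sim <- simulate_facilities(sim_config(), seed = 7)
#' head(sim$facilities)
#' @export
simulate_facilities <- function(config, seed,
                                registry = item_registry(
                                  config$item_difficulty_sd,
                                  seed = substream_seed(seed, "items"))) {
  stopifnot(inherits(config, "qualstab_config"))
  check_registry(registry)
  regions <- region_table(config$n_regions)

  frame <- tidyr::expand_grid(
    pair_set_id = seq_along(config$pair_sets),
    regions,
    tibble::tibble(tier = rep(TIERS, config$facilities_per_stratum))
  )
  frame <- dplyr::group_by(frame, .data$pair_set_id, .data$region, .data$tier)
  frame <- dplyr::mutate(frame, idx = dplyr::row_number())
  frame <- dplyr::ungroup(frame)
  frame$facility_id <- sprintf("f%02d_%s_%s_%03d", frame$pair_set_id,
                               frame$region, frame$tier, frame$idx)

  fac <- with_substream(seed, "facilities", {
    frame$authority <- ifelse(runif(nrow(frame)) < config$private_share,
                              "private", "public")
    frame$urbanicity <- ifelse(
      runif(nrow(frame)) < config$urban_share[frame$tier], "urban", "rural")
    # stratified sampling at wave t0: a fixed round(fraction * n) per stratum
    frame <- dplyr::group_by(frame, .data$pair_set_id, .data$region, .data$tier)
    frame <- dplyr::mutate(
      frame,
      sampled = .data$idx %in% sample.int(
        dplyr::n(), round(config$sampling_fraction[.data$tier[1]] * dplyr::n())))
    frame <- dplyr::ungroup(frame)
    sampled <- frame[frame$sampled, ]
    sampled$resampled <- runif(nrow(sampled)) <
      unname(config$resample_prob[sampled$tier])
    if (config$resample_third_wave) {
      sampled$third_wave <- sampled$resampled &
        runif(nrow(sampled)) < unname(config$resample_prob[sampled$tier])
    } else {
      sampled$third_wave <- FALSE
    }
    sampled
  })

  waves <- purrr::map(config$pair_sets, as.integer)
  rows <- purrr::pmap(
    list(split(fac, fac$pair_set_id),
         waves[sort(unique(fac$pair_set_id))]),
    function(d, w) {
      out <- d[rep(seq_len(nrow(d)), 1L + d$resampled + d$third_wave), ]
      wave_idx <- unlist(purrr::map2(d$resampled, d$third_wave, function(r, t3)
        seq_len(1L + r + t3)))
      out$wave <- w[1] + 2L * (wave_idx - 1L)
      out
    })
  facilities <- dplyr::bind_rows(rows)
  facilities$facility_weight <-
    unname(1 / config$sampling_fraction[facilities$tier])
  facilities$pair_set <- purrr::map_chr(
    facilities$pair_set_id, ~ paste(config$pair_sets[[.x]], collapse = "-"))
  facilities <- facilities[order(facilities$facility_id, facilities$wave), ]

  latent <- with_substream(seed, "latent", {
    draw_latent(facilities, config)
  })

  items <- with_substream(seed, "item_responses", {
    draw_item_responses(facilities, latent, registry, config)
  })

  fac_tbl <- tibble::as_tibble(facilities[, c(
    "facility_id", "wave", "pair_set", "tier", "authority", "region",
    "major_region", "urbanicity", "facility_weight")])
  list(facilities = fac_tbl, readiness_items = items, latent = latent,
       registry = registry)
}

# Latent quality per facility x measure x wave. Wave sequence within a
# facility follows a stationary AR(1) with lag-2-year correlation rho, so
# corr(theta_t, theta_t+2) = rho for every adjacent wave pair.
draw_latent <- function(facilities, config) {
  one <- facilities[!duplicated(facilities$facility_id), ]
  n_waves <- tapply(facilities$wave, facilities$facility_id, length)
  n_waves <- as.integer(n_waves[one$facility_id])
  first_wave <- tapply(facilities$wave, facilities$facility_id, min)
  first_wave <- as.integer(first_wave[one$facility_id])

  out <- purrr::map(MEASURES, function(m) {
    rho <- config$rho[m]
    mu <- config$mu_tier[one$tier]
    sigma <- config$sigma_tier[one$tier]
    z <- matrix(rnorm(nrow(one) * max(n_waves)), nrow = nrow(one))
    theta <- matrix(NA_real_, nrow(one), max(n_waves))
    theta[, 1] <- z[, 1]
    if (max(n_waves) > 1) {
      for (k in 2:max(n_waves)) {
        theta[, k] <- rho * theta[, k - 1] + sqrt(1 - rho^2) * z[, k]
      }
    }
    idx <- cbind(rep(seq_len(nrow(one)), n_waves),
                 unlist(lapply(n_waves, seq_len)))
    tibble::tibble(
      facility_id = rep(one$facility_id, n_waves),
      wave = rep(first_wave, n_waves) + 2L * (idx[, 2] - 1L),
      measure = m,
      theta = unname(rep(mu, n_waves) + rep(sigma, n_waves) * theta[idx])
    )
  })
  dplyr::bind_rows(out)
}

draw_item_responses <- function(facilities, latent, registry, config) {
  reg <- registry[registry$instrument %in%
                    c("readiness_general", "readiness_anc",
                      "readiness_obstetric", "readiness_child", "bemonc"), ]
  reg$measure <- instrument_measure_map[reg$instrument]
  fw <- facilities[, c("facility_id", "wave")]
  grid <- dplyr::inner_join(
    dplyr::inner_join(fw, latent, by = c("facility_id", "wave")),
    reg, by = "measure", relationship = "many-to-many")
  p <- stats::plogis(grid$theta + grid$difficulty)
  if (config$deterministic_items) {
    resp <- as.integer(p > 0.5)
  } else {
    resp <- rbinom(length(p), 1L, p)
    resp[runif(length(p)) < config$item_missing_prob] <- NA_integer_
  }
  tibble::tibble(
    facility_id = grid$facility_id, wave = grid$wave,
    instrument = grid$instrument, item_id = grid$item_id,
    response = resp)
}

#' Simulate direct observations of ANC and child visits
#'
#' For each facility-wave offering a service, draws a small number of
#' observed consultations (1 + Poisson, matching median counts of about five
#' child and three to four ANC visits), a visit-order label for ANC visits,
#' and per-action completion indicators around the facility's latent process
#' quality with extra between-visit noise. Client weights are the inverse
#' within-facility sampling fraction, shared by the visits of a
#' facility-service-wave.
#'
#' @param config a [sim_config()] object.
#' @param facilities facility table from [simulate_facilities()].
#' @param latent latent table from [simulate_facilities()].
#' @param registry the item registry.
#' @param seed master integer seed.
#' @return A tibble in long action format: one row per visit-action with
#'   columns `visit_id`, `facility_id`, `wave`, `service`, `visit_order`,
#'   `client_weight`, `action_id`, `response`.
#' @export
simulate_visits <- function(config, facilities, latent, registry, seed) {
  stopifnot(inherits(config, "qualstab_config"))
  with_substream(seed, "visits", {
    svc <- tibble::tibble(service = c("ANC", "child"),
                          instrument = c("process_anc", "process_child"))
    cells <- tidyr::expand_grid(
      facilities[, c("facility_id", "wave")], svc)
    cells$offered <- runif(nrow(cells)) <
      unname(config$service_offered_prob[cells$service])
    cells <- cells[cells$offered, ]
    if (nrow(cells) == 0L) return(empty_visits())
    cells$n_visits <- 1L + rpois(nrow(cells),
                                 config$visit_rate[cells$service])
    fixed <- config$visit_count_fixed[cells$service]
    cells$n_visits[!is.na(fixed)] <- as.integer(fixed[!is.na(fixed)])
    cells <- cells[cells$n_visits > 0L, ]
    if (nrow(cells) == 0L) return(empty_visits())
    # inverse within-facility sampling fraction: clients presenting that day
    # beyond those observed inflate the weight
    cells$client_weight <- (cells$n_visits + rpois(nrow(cells), 2)) /
      cells$n_visits

    visits <- cells[rep(seq_len(nrow(cells)), cells$n_visits), ]
    visits$visit_seq <- unlist(lapply(cells$n_visits, seq_len))
    visits$visit_id <- sprintf("%s_%d_%s_%02d", visits$facility_id,
                               visits$wave, visits$service, visits$visit_seq)
    visits$visit_order <- NA_character_
    anc <- visits$service == "ANC"
    visits$visit_order[anc] <- sample(
      c("first", "follow_up_2", "follow_up_3", "follow_up_4plus"),
      sum(anc), replace = TRUE, prob = c(0.4, 0.25, 0.2, 0.15))
    visits$visit_noise <- rnorm(nrow(visits), 0, config$visit_noise_sd)

    reg <- registry[registry$instrument %in% svc$instrument, ]
    reg$measure <- instrument_measure_map[reg$instrument]
    visits <- dplyr::inner_join(visits, latent,
                                by = c("facility_id", "wave",
                                       "instrument" = "measure"))
    acts <- dplyr::inner_join(visits, reg,
                              by = "instrument",
                              relationship = "many-to-many")
    p <- stats::plogis(acts$theta + acts$visit_noise + acts$difficulty)
    resp <- rbinom(length(p), 1L, p)
    resp[runif(length(p)) < config$action_missing_prob] <- NA_integer_
    tibble::tibble(
      visit_id = acts$visit_id, facility_id = acts$facility_id,
      wave = acts$wave, service = acts$service,
      visit_order = acts$visit_order, client_weight = acts$client_weight,
      action_id = acts$item_id, response = resp)
  })
}

empty_visits <- function() {
  tibble::tibble(visit_id = character(), facility_id = character(),
                 wave = integer(), service = character(),
                 visit_order = character(), client_weight = double(),
                 action_id = character(), response = integer())
}

#' Simulate DHS-style household records
#'
#' Draws, for each major region and survey year, in-need women (live birth in
#' the past two years) and symptomatic children under five. Each unit gets a
#' reported care source from the configured per-service multinomial over
#' public hospital / health centre / health post, private, health hut or
#' unknown, and none; a share of ANC users reports an additional lower-ranked
#' source; ANC visit counts are drawn so that the configured fraction of
#' users reaches four or more visits. Survey weights are positive and
#' heterogeneous.
#'
#' @param config a [sim_config()] object.
#' @param seed master integer seed.
#' @return A tibble with one row per in-need unit: `unit_id`, `unit_type`,
#'   `major_region`, `survey_year`, `anc_sources` (semicolon-separated),
#'   `anc_visits`, `delivery_source`, `child_source`, `survey_weight`.
#' @export
simulate_households <- function(config, seed) {
  stopifnot(inherits(config, "qualstab_config"))
  with_substream(seed, "households", {
    majors <- unique(region_table(config$n_regions)$major_region)
    cells <- tidyr::crossing(major_region = majors,
                             survey_year = config$household_years)
    n_w <- config$households_per_region["woman"]
    n_c <- config$households_per_region["child"]

    women <- cells[rep(seq_len(nrow(cells)), n_w), ]
    women$unit_type <- "woman_live_birth_2y"
    children <- cells[rep(seq_len(nrow(cells)), n_c), ]
    children$unit_type <- "child_under5_symptomatic_2w"

    draw_source <- function(n, probs) {
      sample(names(probs), n, replace = TRUE, prob = probs)
    }

    anc_main <- draw_source(nrow(women), config$source_probs$ANC)
    # a second, strictly lower-ranked source for some ANC users, so the
    # recoding hierarchy has work to do without shifting assigned shares
    extra <- rep(NA_character_, nrow(women))
    can_extra <- match(anc_main, SOURCE_HIERARCHY)
    has_extra <- !is.na(can_extra) & can_extra < length(SOURCE_HIERARCHY) &
      runif(nrow(women)) < config$multi_source_prob
    if (any(has_extra)) {
      extra[has_extra] <- vapply(can_extra[has_extra], function(k) {
        sample(SOURCE_HIERARCHY[(k + 1):length(SOURCE_HIERARCHY)], 1L)
      }, character(1))
    }
    women$anc_sources <- ifelse(is.na(extra), anc_main,
                                paste(anc_main, extra, sep = ";"))
    is_user <- anc_main %in% SOURCE_HIERARCHY
    visits <- integer(nrow(women))
    visits[anc_main == "health_hut_or_unknown"] <-
      sample(1:3, sum(anc_main == "health_hut_or_unknown"), replace = TRUE)
    if (any(is_user)) {
      reach4 <- runif(sum(is_user)) < config$anc4_fraction[anc_main[is_user]]
      visits[is_user] <- ifelse(reach4,
                                4L + rpois(sum(is_user), 1.2),
                                sample(1:3, sum(is_user), replace = TRUE))
    }
    women$anc_visits <- visits
    women$delivery_source <- draw_source(nrow(women),
                                         config$source_probs$delivery)
    women$child_source <- NA_character_

    children$anc_sources <- NA_character_
    children$anc_visits <- NA_integer_
    children$delivery_source <- NA_character_
    children$child_source <- draw_source(nrow(children),
                                         config$source_probs$child)

    hh <- dplyr::bind_rows(women, children)
    hh$survey_weight <- exp(rnorm(nrow(hh), 0, 0.3))
    hh$unit_id <- sprintf("hh_%06d", seq_len(nrow(hh)))
    hh[, c("unit_id", "unit_type", "major_region", "survey_year",
           "anc_sources", "anc_visits", "delivery_source", "child_source",
           "survey_weight")]
  })
}

#' Simulate a full paired SPA/DHS dataset
#'
#' Convenience wrapper running [simulate_facilities()], [simulate_visits()]
#' and [simulate_households()] on named substreams of one master seed, so
#' that adding or rerunning one stage never perturbs another stage's draws.
#'
#' @param config a [sim_config()] object.
#' @param seed master integer seed.
#' @return A list of class `qualstab_sim` with elements `facilities`,
#'   `readiness_items`, `visits`, `households`, `latent`, `registry`,
#'   `config` and `seed`.
#' @examples
#' sim <- simulate_survey_data(sim_config(), seed = 42)
#' names(sim)
#' @export
simulate_survey_data <- function(config = sim_config(), seed) {
  fac <- simulate_facilities(config, seed)
  visits <- simulate_visits(config, fac$facilities, fac$latent,
                            fac$registry, seed)
  households <- simulate_households(config, seed)
  structure(
    list(facilities = fac$facilities, readiness_items = fac$readiness_items,
         visits = visits, households = households, latent = fac$latent,
         registry = fac$registry, config = config, seed = seed),
    class = "qualstab_sim")
}

#' @export
print.qualstab_sim <- function(x, ...) {
  cat("<qualstab_sim> seed", x$seed, "\n")
  cat("  facility-waves:", nrow(x$facilities), "\n")
  cat("  item responses:", nrow(x$readiness_items), "\n")
  cat("  visit-actions: ", nrow(x$visits), "\n")
  cat("  households:    ", nrow(x$households), "\n")
  invisible(x)
}
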