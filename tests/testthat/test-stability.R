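test_that("pairing emits every 2-year pair and rejects duplicates", {
  fac <- tibble::tibble(
    facility_id = c("a", "a", "b", "b", "b", "c", "c"),
    wave = c(2013, 2015, 2014, 2016, 2018, 2014, 2017),
    tier = "hospital", major_region = "West", facility_weight = 2)
  pairs <- pair_assessments(fac)
  expect_equal(nrow(pairs[pairs$facility_id == "a", ]), 1)
  b <- pairs[pairs$facility_id == "b", ]
  expect_equal(nrow(b), 2)
  expect_equal(sort(b$wave_t0), c(2014, 2016))
  expect_equal(b$cluster_id, c("b", "b"))
  expect_equal(nrow(pairs[pairs$facility_id == "c", ]), 0)

  dup <- dplyr::bind_rows(fac, fac[1, ])
  expect_error(pair_assessments(dup), "duplicate facility-wave")
})

test_that("pairs keep a measure only when both waves have a score", {
  fac <- tibble::tibble(facility_id = c("a", "a"), wave = c(2014, 2016),
                        tier = "hospital", major_region = "West",
                        facility_weight = 2)
  scores <- tibble::tibble(
    facility_id = "a", wave = c(2014, 2016, 2014),
    measure = c("m1", "m1", "m2"), value = c(0.3, 0.5, 0.7))
  ps <- paired_scores(pair_assessments(fac), scores)
  expect_equal(ps$measure, "m1")
  expect_equal(ps$score_t0, 0.3)
  expect_equal(ps$score_t1, 0.5)
})

test_that("paired differences compute mean absolute and net change", {
  paired <- tibble::tibble(
    measure = "m", tier = c("hospital", "hospital"),
    score_t0 = c(0.3, 0.5), score_t1 = c(0.5, 0.3))
  d <- paired_differences(paired)
  expect_equal(d$mean_abs_diff, 0.2)
  expect_equal(d$mean_net_diff, 0.0)

  one <- paired[1, ]
  d1 <- paired_differences(one)
  expect_equal(d1$mean_abs_diff, 0.2)
  expect_equal(d1$mean_net_diff, 0.2)

  same <- dplyr::mutate(paired, score_t1 = score_t0)
  ds <- paired_differences(same)
  expect_equal(ds$mean_abs_diff, 0)
  expect_equal(ds$mean_net_diff, 0)
})

test_that("weighted Pearson matches its definition and edge rules", {
  set.seed(50)
  x <- runif(50); y <- x + rnorm(50, 0, 0.1); w <- runif(50, 0.5, 3)
  expect_equal(weighted_pearson(x, x, w), 1.0)
  expect_equal(weighted_pearson(x, -x, w), -1.0)
  expect_equal(weighted_pearson(x, y, rep(2, 50)), cor(x, y),
               tolerance = 1e-12)
  expect_equal(weighted_pearson(x, y, w), oracle_weighted_pearson(x, y, w),
               tolerance = 1e-12)
  # invariance to weight rescaling and positive affine transforms
  expect_equal(weighted_pearson(x, y, w), weighted_pearson(x, y, 7.3 * w))
  expect_equal(weighted_pearson(2 * x + 1, 0.5 * y - 3, w),
               weighted_pearson(x, y, w), tolerance = 1e-12)

  expect_warning(r2 <- weighted_pearson(x[1:2], y[1:2], w[1:2]), "fewer than 3")
  expect_true(is.na(r2))
  expect_warning(rc <- weighted_pearson(rep(1, 5), y[1:5], w[1:5]),
                 "zero weighted variance")
  expect_true(is.na(rc))
  expect_error(weighted_pearson(x, y, -w), "positive")
})

test_that("strength bands follow the published cut points", {
  expect_equal(strength_label(0.60), "moderate")
  expect_equal(strength_label(-0.32), "weak")
  expect_equal(strength_label(0.05), "negligible")
  # band edges belong to the higher band
  expect_equal(strength_label(c(0.10, 0.40, 0.70, 0.90)),
               c("weak", "moderate", "strong", "very strong"))
  expect_true(is.na(strength_label(NA_real_)))
})

test_that("percent agreement and kappa match closed forms", {
  same <- agreement_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(same$pct_agreement, 1.0)
  expect_equal(same$kappa, 1.0)

  anti <- agreement_kappa(c(1, 1, 2, 2), c(2, 2, 1, 1))
  expect_equal(anti$pct_agreement, 0.0)
  expect_equal(anti$kappa, -1.0)

  l0 <- c(1, 1, 1, 2, 2, 3); l1 <- c(1, 2, 1, 2, 3, 3)
  got <- agreement_kappa(l0, l1)
  expect_equal(got$kappa, oracle_kappa(l0, l1), tolerance = 1e-12)
  skip_if_not_installed("e1071")
  tab <- table(factor(l0, levels = 1:3), factor(l1, levels = 1:3))
  expect_equal(got$kappa, e1071::classAgreement(tab)$kappa,
               tolerance = 1e-12)

  expect_warning(dg <- agreement_kappa(c(1, 1), c(1, 1)), "degenerate")
  expect_true(is.na(dg$kappa))
  expect_equal(dg$pct_agreement, 1.0)
})

test_that("regional values are weighted means and correlate across waves", {
  paired <- tibble::tibble(
    facility_id = c("a", "b"), pair_set = "2014-2016",
    wave_t0 = 2014, wave_t1 = 2016,
    major_region = "West", measure = "readiness_general",
    score_t0 = c(0.2, 0.4), score_t1 = c(0.3, 0.5),
    weight_t0 = c(1, 1), weight_t1 = c(1, 1))
  rs <- regional_scores(paired)
  expect_equal(rs$value_t0, 0.3)
  expect_equal(rs$value_t1, 0.4)

  # anti-ordered regional values across waves give negative correlation
  anti <- tidyr::expand_grid(major_region = c("W", "C", "N", "S"),
                             pair_set = c("p1", "p2"))
  anti$measure <- "m"
  anti$value_t0 <- seq(0.1, 0.8, length.out = 8)
  anti$value_t1 <- rev(anti$value_t0)
  expect_lt(weighted_pearson(anti$value_t0, anti$value_t1), 0)

  # identical waves give r = 1 through the regional summary
  ident <- dplyr::mutate(anti, value_t1 = value_t0)
  reg <- dplyr::reframe(dplyr::group_by(ident, measure), {
    v0 <- value_t0; v1 <- value_t1
    tibble::tibble(r = weighted_pearson(v0, v1))
  })
  expect_equal(reg$r, 1.0)
})

test_that("regional process measures average visits with client weights", {
  paired <- tibble::tibble(
    facility_id = c("a", "b"), pair_set = "2014-2016",
    wave_t0 = 2014, wave_t1 = 2016, major_region = "West",
    measure = "process_child",
    score_t0 = c(0.25, 0.75), score_t1 = c(0.5, 0.5),
    weight_t0 = 1, weight_t1 = 1)
  visit_scores <- tibble::tibble(
    visit_id = as.character(1:4),
    facility_id = c("a", "a", "b", "b"),
    wave = c(2014, 2016, 2014, 2016),
    service = "child", visit_order = NA_character_,
    client_weight = c(1, 1, 3, 1), score = c(0.2, 0.6, 0.6, 0.8))
  rs <- regional_scores(paired, visit_scores)
  expect_equal(rs$value_t0, (0.2 * 1 + 0.6 * 3) / 4)
  expect_equal(rs$value_t1, 0.7)
})

test_that("weight-wave sensitivity is null under proportional weights", {
  set.seed(60)
  paired <- tibble::tibble(
    measure = "m", score_t0 = runif(30), score_t1 = runif(30),
    weight_t0 = runif(30, 1, 5))
  paired$weight_t1 <- paired$weight_t0 * 4
  sw <- sensitivity_weights(paired)
  expect_equal(sw$r_earlier, sw$r_later, tolerance = 1e-12)
  expect_equal(sw$r_diff, 0, tolerance = 1e-12)

  # imbalanced later-wave weights change the estimate (no sign asserted)
  paired$weight_t1 <- c(rep(10, 5), rep(0.1, 25))
  sw2 <- sensitivity_weights(paired)
  expect_equal(sw2$r_later,
               oracle_weighted_pearson(paired$score_t0, paired$score_t1,
                                       paired$weight_t1),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sw2$r_earlier, sw2$r_later)))
})

test_that("quality_stability bundles facility, tier and regional summaries", {
  cfg <- small_config()
  sim <- simulate_survey_data(cfg, seed = 33)
  scores <- score_facilities(sim)
  pairs <- pair_assessments(sim$facilities)
  fit <- suppressWarnings(
    quality_stability(pairs, scores,
                      visit_scores = score_visits(sim$visits, sim$registry)))
  expect_s3_class(fit, "qualstab_stability")
  expect_true(all(unique(fit$facility$measure) %in% unique(scores$measure)))
  expect_true(all(fit$facility$pct_agreement >= 0 &
                    fit$facility$pct_agreement <= 1, na.rm = TRUE))
  expect_true(all(abs(fit$facility$pearson_r) <= 1, na.rm = TRUE))
  expect_true(all(fit$facility$kappa <= 1, na.rm = TRUE))
  td <- tidy(fit)
  expect_identical(td, fit$facility)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
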