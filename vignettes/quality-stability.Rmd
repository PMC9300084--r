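---
title: "Stability of facility quality measures and adjusted coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability of facility quality measures and adjusted coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 5)
library(qualstab)
library(dplyr)
```

## The measurement problem

Health-facility assessments such as the Service Provision Assessment (SPA)
are detailed but infrequent. Their quality measures — structural readiness
indices, adherence to clinical guidelines observed during consultations,
reported performance of emergency obstetric signal functions — are routinely
used months or years after collection, for benchmarking facilities and for
computing *effective coverage*: the share of a population in need that
reaches a service, discounted by the quality of the facilities it reaches.
Both uses presume the measure still describes the facility at the time of
inference. `qualstab` provides a tested pipeline for quantifying that
presumption: it measures the test–retest stability of facility quality
scores across repeated assessments two years apart, and propagates any
instability into input-adjusted and quality-adjusted coverage estimates.

Because the microdata that motivate this design are restricted-access, the
package ships a synthetic-data generator that emulates their statistical
structure, and every analysis stage is exercised end to end on generated
data.

## Quality measures

Seven measures are computed per facility and wave, each a continuous score
in $[0,1]$:

* **Readiness indices** (structural quality), SARA-style: general services
  (48 items), antenatal care (9), basic obstetric care (19) and child care
  (18). The score is the proportion of items present out of items assessed:
  $s = \sum_i x_i / n_{\text{assessed}}$, with missing responses excluded
  from the denominator. A `domain_mean` variant (the unweighted mean of
  domain proportions, the classic SARA index form) is available through
  `readiness_aggregation`; the instruments' published aggregation is not
  specified at item level, so the pooled item mean is the default, matching
  the "proportion completed of assessed" form used for process scores.
* **Process adherence** from direct observation: 27 ANC actions and 25
  child-visit actions. A visit's score is the weighted proportion of
  assessed actions completed; actions in ANC *follow-up* visits carry
  weights 1/3, 2/3 or 1 according to how many of recommended visits 2–4
  call for them, while first ANC visits and child visits weigh all actions
  equally. Facility scores are the client-weight-weighted mean of visit
  scores.
* **BEmONC signal functions**: the proportion of the 7 Basic Emergency
  Obstetric and Newborn Care signal functions reported performed in the
  prior 3 months, with a fixed denominator of 7.

For classification stability, scores are cut into **tertiles of the
observed range** separately for each measure and wave year: the range
$[\min, \max]$ is split into three equal-width intervals, boundaries belong
to the lower interval and the maximum to the top tertile — a deterministic,
order-free rule. A zero-width range assigns everyone the middle tertile
with a warning.

## Stability analysis

Assessments of the same facility exactly two years apart are paired
(`pair_assessments()`); a facility seen at three eligible waves contributes
two pairs and carries a cluster id. Per measure, a pair enters the analysis
only if both waves have a score. The summaries are:

* mean absolute difference $\overline{|s_1 - s_0|}$ and mean net difference
  $\overline{s_1 - s_0}$, overall and by tier or major region;
* the **design-weighted Pearson correlation**, weighted by the facility
  sampling weight of the *earlier* wave (a sensitivity variant uses the
  later wave's weights), with strength bands negligible $<0.10$, weak
  $0.10$–$0.39$, moderate $0.40$–$0.69$, strong $0.70$–$0.89$, very strong
  $0.90$–$1.00$ applied to $|r|$ (band edges to the higher band);
* **percent agreement** and unweighted **Cohen's kappa** of tertile
  classifications, $\kappa = (p_o - p_e)/(1 - p_e)$ with $p_e$ from the
  product of marginal label distributions over the observed categories;
* **regional stability**: scores averaged to the four major regions within
  the paired panel — facility-weighted means of facility scores for
  structural and signal-function measures, client-weighted means over all
  observed visits for process measures — then correlated across the
  region-by-pair-set points.

Degenerate cases are flagged, never zero-filled: correlations on fewer than
3 points or with zero weighted variance, and kappa with degenerate margins,
are returned as missing with a warning.

## Adjusted coverage

Contact coverage per service is the survey-weighted share of the in-need
population (women with a live birth in the past 2 years for ANC 1/ANC 4 and
delivery; children under 5 with recent fever, diarrhoea or respiratory
symptoms for child care) whose reported source is a hospital, health centre,
health post or private facility — with at least 1 or 4 visits for ANC 1 and
ANC 4. Women reporting several ANC sources are assigned the highest type in
the order public hospital > public health centre > public health post >
private; health huts and unclassifiable sources count as not receiving
services.

Adjusted coverage is the share-weighted sum over facility types of the
type's mean quality,
$\tilde{C} = \sum_t p_t \, \bar{q}_t \le C = \sum_t p_t$,
computed nationally and by major region. Quality strata are
facility-weighted means among the paired-panel facilities assessed in the
service's reference wave (one year before the interview year for maternal
services, the same year for child services); the `t_minus_2` twin uses the
same facilities' assessment two years earlier. Regional estimates are kept
only when the region has at least one facility of every type respondents
reported using. Differences between the two references are reported as
linear ($100\,|E_t - E_{t-2}|$ percentage points) and relative
($100\,|E_t - E_{t-2}|/E_t$) differences, summarised as medians and IQRs.

Two open design choices are resolved as follows. National stratum
qualities pool facilities nationally by type (regional estimates use
region-by-type means); and delivery sources are taken as single reports, so
the multi-source hierarchy applies only to ANC. ANC 4 shares ANC 1's
quality measures — no separate instrument exists — and differs only through
its contact-coverage condition.

## What the generator emulates

`sim_config()` encodes the study conditions: 14 regions mapped 2/4/3/5 to
the West/Centre/North/South major regions; per-tier sampling fractions 0.5
(hospitals, health centres) and 0.2 (health posts), so design weights are
2 and 5; resampling two years later with certainty for hospitals and health
centres and probability 0.3 for health posts (non-resampled posts drop out
of the paired panel); four wave pairs, 2013–2015 through 2016–2018.

Latent quality per facility and measure lives on the logit scale:
$\theta_{t_0} = \mu_{\text{tier}} + \sigma_{\text{tier}} z_0$ and
$\theta_{t_1} = \mu_{\text{tier}} + \sigma_{\text{tier}}(\rho z_0 +
\sqrt{1-\rho^2}\, z_1)$, so the persistent component $\rho z_0$ is the
shared facility effect and $\mathrm{corr}(\theta_{t_0}, \theta_{t_1}) =
\rho$ exactly, with a single controllable reliability parameter per
measure (default 0.6). Item and action responses are conditionally
independent Bernoulli draws around $\theta$ plus a per-item difficulty
drawn once and fixed across waves — so items as well as facilities spread
the scores, and finite item and visit samples *attenuate* score-level
correlation below $\rho$, the mechanism whose consequences the stability
analysis measures. Observed visit counts are $1 + \text{Poisson}$ with
rates 2.8 (ANC) and 4.5 (child), giving median counts of about 3–4 and 5;
between-visit noise (SD 0.7 on the logit scale) makes small visit samples
genuinely noisy.

Household records follow per-service multinomials over reported sources
chosen so that contact coverage is near 94% (ANC 1), 50% (ANC 4), 74%
(delivery) and 36% (child care), with health posts capturing roughly 71%,
56% and 80% of ANC, delivery and child users respectively; survey weights
are heterogeneous log-normals. One master seed spawns named substreams
(items, facilities, latent, visits, households), so rerunning or adding a
stage never perturbs another stage's draws.

The generator does **not** emulate geographic coordinates, seasonality,
the 2017 sampling-frame refresh, the restriction of ANC observation to
alternating survey years, or real DHS two-stage cluster sampling beyond
carrying unit weights. Passing tests on generated data therefore
demonstrate the correctness and internal consistency of the estimators —
not the field properties of any real survey.

## Worked example

```{r pipeline, warning = FALSE}
res <- run_pipeline(sim_config(), seed = 1)
tidy(res$stability)
glance(res)
```

```{r autoplot}
ggplot2::autoplot(res$stability)
```

```{r coverage}
res$coverage_summary %>%
  select(service, adjustment, n, linear_diff_median, relative_diff_median)
plot_coverage_differences(res$coverage_differences)
```

## Numerical choices and limitations

* Problem sizes: the default configuration yields roughly 400 paired
  assessments and a few thousand household records per survey year —
  commensurate with a national continuous facility survey, and chosen once
  as the package's standard study condition.
* Undefined statistics propagate as `NA` with warnings; they are never
  silently replaced by 0.
* Tertile ties: left-closed equal-width intervals with the maximum in the
  top tertile.
* Facilities contributing two pairs (third-wave resampling, off by
  default) are retained in correlations without cluster adjustment;
  cluster ids are emitted so users can bootstrap by facility.
* Item identities are abstract: the registry carries instrument
  membership, domain labels and counts, not real instrument item lists,
  and which ANC actions carry weight 1/3 vs 2/3 is configurable rather
  than fixed.
* No confidence intervals are computed for correlations, kappa or adjusted
  coverage; point estimates are the object of study.
* CSV outputs write doubles with 15 significant digits so that
  write–read–write cycles are byte-stable.
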