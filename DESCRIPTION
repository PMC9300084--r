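Package: qualstab
Title: Stability of Facility Quality-of-Care Measures and Adjusted Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the temporal stability of health-facility
    quality-of-care measures and its propagation into input- and
    quality-adjusted (effective) coverage estimates. Provides a synthetic-data
    generator emulating paired Service Provision Assessment (SPA) facility
    surveys and Demographic and Health Survey (DHS) household records;
    SARA-style readiness scoring, direct-observation process scoring, BEmONC
    signal-function scoring and equal-width tertile classification; paired
    stability analysis (weighted Pearson correlation, percent agreement,
    Cohen's kappa, absolute and net differences) at facility and regional
    level; and survey-weighted linkage of household contact coverage to
    facility quality by source-type strata, with difference metrics between
    coverage estimates built from assessments two years apart.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
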