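Package: mealscan
Title: Meal Microstructure and Indirect Calorimetry Analysis for Metabolic
    Cage Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segmentation of continuous feeding-event logs from metabolic
    cages (CLAMS-style hopper interaction records) into meals, with the
    canonical meal-level parameters (meal size, duration, ingestion rate,
    intermeal interval and satiety ratio), circadian light/dark and
    zero-intake summaries, evoked feeding-response windows (dark onset,
    fast-refeed, ghrelin), indirect-calorimetry energetics (respiratory
    exchange ratio, Lusk caloric value, heat production) and ambulatory
    beam-break analysis.  Includes the cohort-level statistical layer used
    in cachexia phenotyping (linear mixed models with animal random
    intercepts, paired tests, one-tailed exact proportion tests) and a
    seeded stochastic generator that emulates healthy-baseline and
    cachectic (KPC day-14) mice so the full pipeline runs without
    proprietary instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
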