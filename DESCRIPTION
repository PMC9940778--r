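Package: mobitriad
Title: Compare Survey, GSM, and GPS Mobility Measures on a Common Synthetic Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a population whose daily mobility is driven by a latent,
    policy-stringency-modulated activity process and observes it through three
    measurement channels: mobile-network (GSM) localization events summarised by
    the time-weighted radius of gyration, GPS-style place-category visit indices
    in the Community Mobility Report percent-change-from-baseline format, and a
    multi-wave panel survey of self-reported activity frequencies. Provides
    poststratification raking (iterative proportional fitting), harmonization of
    all channels to baseline-relative weekly changes matched to survey waves,
    and a comparison layer with Pearson correlations, trend lines,
    time-fixed-effects regression, and a difference-in-differences estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    ggplot2,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
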