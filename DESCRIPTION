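Package: gaitsampen
Title: Sample Entropy of Treadmill Gait Signals Under Different
    Preprocessing Regimes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the regularity of treadmill walking signals
    (anterio-posterior and medio-lateral centre-of-pressure trajectories and
    the resultant vertical ground reaction force) with Sample Entropy.
    Provides a synthetic treadmill-gait generator, stride segmentation from
    the vertical force channel, the four canonical signal preparations
    (raw, stride-segmented and time-resampled, additionally spatially
    normalised, additionally per-stride zeroed), an exact Richman-Moorman
    Sample Entropy implementation with match-count transparency and a
    template-length/tolerance grid, spectral support for choosing a
    biologically meaningful template length, balanced two-way and mixed
    ANOVA over the resulting sensitivity table, and a pipeline that runs the
    whole speed-discrimination experiment end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
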