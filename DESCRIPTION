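Package: coageing
Title: Co-Ageing Interdependency Networks and the Demography of Coupled Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates pairs of directed interdependency networks that damage
    each other in proportion to their functional fractions, producing the
    non-monotonic ("kink/bump") all-cause and cause-specific hazard curves
    characteristic of co-ageing cohorts such as infected worms, competing
    trees, and chess games.  Provides network growth by random in/out
    attachment, a two-round damage/propagation/repair engine with per-cause
    failure tagging, discrete-time competing-risks demography, Glicko
    expected-outcome computation with a PGN chess-archive pipeline, parameter
    sweeps, and simulation-based calibration to empirical hazard curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
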