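Package: benefitsim
Title: Simulation-Based Comparison of Additional Benefit Assessment
    Methods for Survival Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates phase-III two-arm survival trials (exponential, Weibull,
    Gompertz and piecewise-exponential delayed-effect failure times, Schoenfeld
    event sizing, administrative plus calibrated exponential censoring) and
    applies four additional-benefit assessment rules to every significant
    trial: the continuous ASCO net-health-benefit score built from the hazard
    ratio point estimate, the ordinal IQWiG and modified IQWiG categories built
    from the upper confidence limit, and the ordinal ESMO magnitude-of-
    clinical-benefit grade built from the lower confidence limit together with
    the absolute gain in median survival. Scored replicate pools are compared
    with rank correlations and weighted Cohen's kappa, and ASCO score cutoffs
    concordant with each ordinal scale are derived by exhaustive kappa
    maximisation, ROC distance-to-corner and Svensson marginal matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    parallel,
    pracma,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
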