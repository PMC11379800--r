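Package: leapfrog
Title: Design Analysis and Simulation for 'Leapfrog' Adaptive Platform Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to plan, calibrate and simulate 'leapfrog' adaptive platform
    trials, in which challenger treatment arms are compared to a contemporaneous
    comparator arm by directional sequential Jeffreys-Zellner-Siow (Cauchy prior)
    two-sample t-test Bayes factors, and are dropped at a failure boundary,
    promoted to become the new comparator at a success boundary, or retired at a
    per-arm sample-size cap. Provides the directional Bayes-factor engine with a
    Monte-Carlo verification oracle, pairwise sequential design analysis with
    Monte-Carlo operating characteristics (power and false-positive rate by
    accumulating sample size), a multi-arm trial engine with mid-trial arm entry
    and deterministic scenario replay, classical fixed-N sample-size comparators,
    and configuration/report input-output with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
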