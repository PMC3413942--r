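Package: rrdesign
Title: Simulation and Estimation for Repeated-Randomizations Crossover Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying treatment response heterogeneity (TRH) with
    the repeated-randomizations design (RRD), in which every subject is
    re-randomized to treatment or control at each of p periods. Provides a
    potential-outcomes simulator with subject random intercepts, random
    subject-treatment interactions, fixed period effects and first-order
    carryover; allocation schedule builders for parallel-groups, two-period
    crossover, Balaam and RRD trials; moment and mixed-model estimators of
    individual treatment effects, the TRH variance and normal-model responder
    proportions; Monte-Carlo relative-efficiency comparisons between designs;
    and analysis utilities for ordinal patient-preference surveys (reverse
    scoring, paired Wilcoxon signed-rank tests, Wald proportion intervals)
    together with a correlated-ordinal synthetic survey generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
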