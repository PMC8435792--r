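Package: metdose
Title: Bayesian Evaluation of Minimal-Dose Strength Training Against an
    Elicited Region of Practical Equivalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating minimal effective training dose (METD)
    interventions in powerlifting. Builds a distributional region of
    practical equivalence (ROPE) from expert-elicited minimal meaningful
    strength changes via an intercept-only Bayesian model, fits
    change-score ANCOVA models with informed or chained priors and a
    nested multilevel internal meta-analysis (all via JAGS), and compares
    posterior effect distributions against the ROPE using kernel-density
    modes, highest-density intervals, probability-of-superiority (ROC
    AUC) and density-overlap statistics. Includes a synthetic-data
    generator for elicitation surveys and quasi-randomized two-arm
    training cohorts, training-protocol volume accounting, Wilks scoring
    and strength-class allocation, and an end-to-end reproducible
    pipeline with descriptive summaries and posterior-versus-ROPE plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
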