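Package: nestpheno
Title: Phenology-Corrected Vegetation Covariates and Daily Nest Survival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diagnosing and removing the measurement-timing bias
    that arises when vegetation surrounding ground nests is measured at the
    date a nest's fate is discovered: because successful nests persist, they
    are measured later in the season than failed nests, and concurrent plant
    growth then masquerades as an effect of concealment on nest survival.
    The package simulates multi-site nest studies with within-season grass
    phenology and configurable measurement protocols, corrects measured
    grass heights to predicted hatch date via per-stratum growth
    regressions, fits Bayesian daily nest-survival models with an exact
    interval-censored Bernoulli likelihood and an adaptive Metropolis
    sampler, derives incubation-period nest-success curves over grass
    height, and runs pooled mixed-model, likelihood-ratio, and one-sided
    Kolmogorov-Smirnov comparisons of successful versus failed nests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    ggplot2,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
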