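Package: parasitoidQG
Title: Quantitative Genetics of Parasitoid Performance on a Novel Host
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for count-based parasitization performance assays and their
    quantitative-genetic analysis in haplodiploid parasitoids tested on a
    novel host. Computes day-standardized attack, killing, lethal-attack and
    successful-parasitism indices from vial-level counts; builds haplodiploid
    additive relatedness matrices from pedigrees (validated against a
    gene-dropping oracle); fits a Bayesian liability-threshold animal model
    for binomial traits with animal, testing-day and mother random effects, a
    parameter-expanded chi-square(1) prior on variance components and fixed
    unit residual variance; simulates multi-generation truncation-selection
    experiments on killing rate under a drifting host-fitness environment;
    and estimates realized heritability from cumulative selection
    differentials and responses, with breeder's-equation projections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
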