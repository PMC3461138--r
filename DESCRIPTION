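Package: chronopop
Title: Temporal Population Genetics of Microsatellite Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of diploid microsatellite genotypes sampled from the
    same populations at different points in time. Provides Genepop-format
    input/output and S4 containers for heterochronous datasets; within-sample
    diversity statistics (unbiased expected heterozygosity, rarefied allelic
    richness, Hardy-Weinberg exact tests) with locus-paired nonparametric
    comparisons across sampling periods; pairwise differentiation (Weir and
    Cockerham theta, G_ST, standardized G_ST, Jost's D) with permutation
    significance; a serial-sample coalescent simulator of microsatellite loci
    under two-epoch bottleneck demographies with a generalized stepwise
    mutation model; approximate Bayesian computation for scenario choice and
    regression-adjusted parameter posteriors; and temporal-method effective
    population size estimation (moment estimator and pseudo-maximum-likelihood,
    closed or jointly with a migration rate from a fixed source pool).
    Includes forward Wright-Fisher generators for validation fixtures and a
    config-driven study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    nnet,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
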