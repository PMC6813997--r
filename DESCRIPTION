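Package: convergr
Title: Detecting and Quantifying Convergent Evolution in Phylogenetic Shape Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting phenotypic convergence from landmark-based
    shape data on a time-calibrated phylogeny. Implements generalised Procrustes
    alignment with sliding semilandmarks and principal component analysis of
    shape; the multivariate phylogenetic-signal statistic K_mult with a
    permutation test; Brownian-motion and multi-peak Ornstein-Uhlenbeck (Hansen)
    model likelihoods with a two-phase stepwise AICc search for convergent
    adaptive regimes; Stayton's distance-based convergence measures C1-C4 with
    Brownian-motion simulation nulls; the Wheatsheaf index of convergence
    strength with jackknife confidence intervals and bootstrap p-values; and
    chi-square / ANOVA tests of association between regime membership and
    species ecology. A seeded synthetic-data generator produces trees, regime
    paintings, traits, landmark sets and ecology tables with the statistical
    structure the analysis assumes, so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
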