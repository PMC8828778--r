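Package: cici
Title: Quantitative Analysis of Chemically Induced Chromosomal Interactions
Version: 1.0.0
Authors@R:
    person("CICI", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying chemically induced chromosomal
    interactions (CICI) in budding yeast from dual-color locus-tracking
    microscopy and companion assays. Implements two-channel spot detection
    and co-localization measurement on z-stacks, rule-based calling of
    contact formation and disruption events in single-cell distance traces,
    fitting of population co-localization time courses with a
    convolution-of-Poisson-processes model, exponential-mixture maximum
    likelihood with AIC model selection for single-cell formation times,
    correlation of contact metrics with Hi-C signals, qPCR-based DNA
    replication timing quantification, and gel-band donor-usage fractions.
    A synthetic-data generator with known ground truth (confined-diffusion
    distance traces, Gaussian-dot z-stacks, binomial population time
    courses, sigmoidal qPCR copy-number tables) makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
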