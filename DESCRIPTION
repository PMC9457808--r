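Package: qstr
Title: Quantitative Structure-Toxicity Modeling for Carbamate Pesticides
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative structure-toxicity relationship (QSTR)
    analysis of carbamate acetylcholinesterase inhibitors. Computes the
    topological, geometric and drug-likeness descriptors of a published
    ten-descriptor multi-linear model of oral rat LD50 toxicity (lopping
    centric index, GETAWAY H4m autocorrelation, inverse-squared-distance
    spectral sum, tertiary-carbon and carbamate substitution counts, lag-5
    atom-pair flags, fifth drug-like score), derives conceptual-DFT
    reactivity indices from frontier-orbital energies, fits and validates
    multi-linear toxicity models (R2, leave-one-out Q2, k-fold
    cross-validation, genetic-algorithm descriptor selection), delimits the
    applicability domain by leverage (Williams plot), and ships the
    published model as a frozen predictor of log(1/C). A seeded synthetic
    data generator emulates the statistical structure of the carbamate
    descriptor matrix for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    graphics,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
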