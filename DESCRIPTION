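Package: crossomics
Title: Paired Crossover Safety Analysis of Mucosal Proteome and Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis toolkit for placebo-controlled crossover
    safety studies of topical products that sample both the mucosal proteome
    and the microbiome. Provides a label-free proteomics paired
    differential-expression pipeline (total-signal and median normalization,
    technical-replicate coefficient-of-variation filtering, interquartile-range
    outlier reporting, baseline averaging, paired t tests with
    Benjamini-Hochberg false-discovery-rate control, and correlation-distance
    hierarchical clustering); two Bayesian paired models for microbiome data
    (a normal-Laplace model on logit-transformed Shannon diversity and a
    binomial logistic-normal relative-abundance model with a
    positive-control-calibrated measurement-error layer); shared inference
    machinery (MCMC sampling with potential-scale-reduction diagnostics, power
    computations for paired designs); and a synthetic-study generator that
    reproduces the design's statistical structure so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    rjags,
    coda,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    biomformat,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
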