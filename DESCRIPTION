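Package: rnakinetics
Title: Kinetic Modeling of RNA Synthesis, Processing and Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the gene-level RNA life cycle as a system of ordinary
    differential equations for premature and mature RNA driven by
    time-dependent kinetic rates of synthesis, processing and degradation.
    Each rate is parameterized as a constant, sigmoid or impulse function of
    time. The package simulates expression trajectories from user-defined
    rates, fits rate-function parameters to replicated expression time
    courses (with or without nascent-RNA synthesis measurements) by weighted
    least squares, scores fits with two-tailed chi-squared p-values and the
    Akaike information criterion, compares alternative regulatory models,
    and computes profile-likelihood confidence intervals. A synthetic-data
    generator provides ground-truth models and noisy replicated profiles,
    and a command-line interface exposes the simulate/fit/select workflow.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
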