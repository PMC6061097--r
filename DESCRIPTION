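Package: tmddesign
Title: Design Evaluation and Optimization for Target-Mediated Drug
    Disposition Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate and optimize sampling designs for population
    pharmacokinetic-pharmacodynamic studies of antibodies against soluble
    targets described by a quasi-equilibrium target-mediated drug
    disposition (TMDD) model. Implements the population Fisher information
    matrix under the first-order approximation with the reduced
    (block-diagonal) parameterization, D-efficiency comparisons between
    candidate and reference designs, a deterministic line-search
    optimization of sampling times on a discretized grid, a population
    simulator with log-normal inter-individual variability, stochastic
    simulation-estimation (SSE) for empirical parameter precision,
    population prediction areas for free-target suppression, and a
    decision-theoretic metric for dose-selection errors. Ships a synthetic
    omalizumab-IgE parameterization calibrated to published summary
    characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
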