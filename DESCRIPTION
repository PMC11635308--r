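Package: thermocompete
Title: Temperature-Dependent Lotka-Volterra Competition with Skewed
    Thermal Performance Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates interspecific Lotka-Volterra competition among
    species whose intrinsic growth rates follow skewed (right-asymmetric)
    thermal performance curves.  Communities are defined as one-row-per-
    species data frames; the package integrates the competition system to
    steady state at fixed environmental temperatures, sweeps a continuous
    temperature range to map which species dominates where, and runs
    seeded robustness ensembles over curve skewness, optimum spacing,
    normalization, and pairwise species subsets.  Results come back as
    tidy tibbles with broom-style tidy()/glance() methods and ggplot2
    autoplot() figures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
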