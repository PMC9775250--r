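Package: sigbswitch
Title: Kinetic Simulation of the Bacillus subtilis SigB Partner-Switching
    Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reconstructs the instantaneous amounts of free and complexed
    sigma factor B (SigB), its anti-sigma factor RsbW and anti-anti-sigma
    factor RsbV in Bacillus subtilis from measured total-expression time
    series.  Total expression profiles of the SigB operon genes and of the
    stress phosphatases RsbU and RsbP force a mass-action ordinary
    differential equation model of the partner-switching network; the
    package provides the preprocessing pipeline (shape-preserving
    interpolation, Gaussian smoothing, numerical differentiation), an
    adaptive Runge-Kutta 2(3) integrator wrapper, perturbation scans over
    phosphatase dose and the k5-/k5+ and k6-/k6+ binding-constant ratios,
    a synthetic microarray time-course generator for testing, and tidy
    reporting with ggplot2 figures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
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
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
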