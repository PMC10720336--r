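Package: verletdiag
Title: Diagnostics for Neighbor-List Artifacts in Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, explains, and helps prevent Verlet neighbor-list
    artifacts in molecular dynamics simulations.  Provides an analytic and
    Monte-Carlo model of missed pair interactions between neighbor-list
    updates (with a buffer-size recommendation engine), pressure time-series
    diagnostics (running averages, phase averages aligned to list updates,
    the before/after-update pressure difference, and Welch power spectra
    with harmonic detection), chi-squared tests of box-shape isotropy,
    Helfrich bending-energy estimation for membrane height fields, and a
    minimal instrumented Lennard-Jones simulator that reproduces the
    artifacts at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
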