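Package: isingfc
Title: Generalized Ising Model Analysis of Brain Structure-Function Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates generalized Ising model spin dynamics on weighted
    structural connectomes with Metropolis Monte Carlo, locates the critical
    temperature from the magnetic susceptibility peak, fits the temperature at
    which simulated functional connectivity best reproduces empirical BOLD
    correlation matrices (Mantel test), and estimates a connectome-distance
    power-law dimensionality. Includes a synthetic cohort generator (geometric
    and lesioned connectomes with paired BOLD-like scans) and the group-level
    statistical battery (Welch t, paired t, one-way ANOVA, Benjamini-Hochberg
    FDR) for comparing model parameters across cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
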