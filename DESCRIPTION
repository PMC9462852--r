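Package: popencycle
Title: Single-Channel Open-Probability Analysis and Thermodynamic Cycles of
    Agonist Efficacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and idealization of single-channel patch-clamp
    recordings of ligand-gated ion channels, segmentation of activity into
    clusters bounded by desensitized periods, per-cluster open-probability
    (Popen) estimation, conversion of Popen to gating equilibrium constants,
    thermodynamic-cycle analysis of agonist efficacy with bootstrap
    uncertainty, nonparametric randomization tests, Hill-equation
    dose-response fitting with rundown-based cell exclusion, and
    Henderson-Hasselbalch protonation arithmetic for acidic-pH agonist
    protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
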