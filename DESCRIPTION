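Package: atriasim
Title: In Silico Trials of Ablation and Drug Therapy in Virtual Atrial
    Fibrillation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale in-silico trial pipeline for persistent atrial
    fibrillation. Builds virtual-patient cohorts with variability in ionic
    currents, atrial size and low-voltage-area (LVA) structure; simulates
    re-entrant arrhythmia with a monodomain reaction-diffusion solver
    coupled to a human atrial action-potential model; applies virtual
    catheter-ablation lesion sets and pore-block antiarrhythmic drugs; and
    tabulates treatment efficacy together with a feature-based patient
    stratification rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
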