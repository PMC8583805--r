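Package: mcdamage
Title: Monte Carlo Simulation of Clustered DNA Damage, Excision Repair
    Outcomes and Radiation Quality Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the induction and clustering of DNA lesions by
    ionising radiation, classifies clustered damage into the standard
    seven-category taxonomy (base damage, simple and complex single-strand
    breaks, simple and complex double-strand breaks), and models the
    excision-repair fate of non-DSB clusters (correct repair, mutation, or
    enzymatic conversion to a double-strand break) for short- and
    long-patch base excision repair with or without nucleotide excision
    repair. Includes a synthetic secondary-electron spectrum generator for
    ultrasoft X-ray lines and Compton-dominated gamma sources, a
    low-energy electron stopping-power model for liquid water, a Hill-type
    oxygen response for hypoxic scaling of damage yields, and the
    dose-weighted quality metrics built on these pieces: hypoxia reduction
    factors (HRF) and relative biological effectiveness (RBE) for damage
    induction and enzymatic DSB formation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
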