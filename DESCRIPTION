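Package: atrazfba
Title: Constraint-Based Simulation of Atrazine Biodegradation by
    Paenarthrobacter aurescens TC1
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Flux balance analysis (FBA), flux variability analysis (FVA)
    and time-stepped dynamic growth/degradation simulation for genome-scale
    metabolic models, organised around the study of atrazine biodegradation
    by Paenarthrobacter aurescens TC1. Reads and writes SBML (Level 3 with
    the flux-bounds/objective extension, plus a legacy fallback) and
    delimited model tables; audits elemental balance, energy-generating
    loops and carbon/nitrogen requirements; screens single-compound media
    supplements and carbon-by-nitrogen uptake gradients; encodes the
    hydrolytic atrazine degradation pathway (TrzN, AtzB, AtzC and alkylamine
    catabolism) as a balanced, injectable reaction set; and computes
    equimolar-nitrogen doses for in vitro media design. Ships analytic toy
    fixtures and a seeded generator of mass-balanced random networks so the
    whole pipeline is testable offline.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
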