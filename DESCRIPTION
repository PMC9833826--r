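Package: strainqtl
Title: Systems Genetics of Protein Abundance in Inbred Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mixed-model quantitative trait locus (QTL) mapping and systems-genetics
    integration for proteomic and phenotypic data from renewable inbred strain panels
    such as the Hybrid Mouse Diversity Panel. Implements identity-by-state kinship
    estimation, restricted maximum likelihood (REML) linear mixed-model association
    scans with q-value false discovery control, cis/trans pQTL classification and
    trans-hotspot detection, biweight-midcorrelation protein-trait networks,
    single-component orthogonal partial least-squares (OPLS) trait modelling, and a
    three-step pQTL/pheQTL integration that prioritizes candidate causal proteins.
    A seeded synthetic-panel generator with a planted-effect truth ledger provides a
    fully reproducible test surface for every stage.
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
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
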