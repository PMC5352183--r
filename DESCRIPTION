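Package: tp53pancan
Title: Pan-Cancer TP53 Mutation, Expression and Synthetic-Lethality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for integrating somatic TP53 mutation calls
    with tumor/normal expression profiles across many cancer types.
    Computes per-cancer TP53 mutation rates and ranks, variant-class
    profiles, and clinical-phenotype associations; derives the
    mutant/wildtype/normal differential-expression gene classes
    (TP53-MW, -WN, -WN2, -MN, -MWN, -MSN) and TP53 co-expression sets
    (PCOR/NCOR) with cytoband over-representation; stratifies
    Kaplan-Meier survival by mutation and expression status; and screens
    for TP53 synthetic-lethality candidates with pharmacogenomic IC50
    validation. Ships a synthetic multi-cancer cohort generator with
    fully known planted structure so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
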