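Package: fhyield
Title: Combined Monogenic and Polygenic Characterization of Familial
    Hypercholesterolemia Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genetic characterization of clinically
    diagnosed familial hypercholesterolemia (FH) cohorts. Implements rare
    variant triage (gnomAD PopMax filtering-allele-frequency filter, ClinVar
    star-rating trust rules, ACMG/AMP evidence combination, and promotion
    screening for high-priority variants of uncertain significance),
    polygenic score computation from PGS-Catalog scoring files with allele
    reconciliation and reference-cohort percentile normalization, and
    cohort-level classification of patients into genetically explained
    (monogenic or polygenic) versus unexplained hypercholesterolemia, with
    diagnostic-yield arithmetic, rank-based AUC and quartile-homogeneity
    statistics. Ships a seeded synthetic-data generator emulating a
    patient/control whole-genome-sequencing study so every stage is testable
    without access to restricted raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
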