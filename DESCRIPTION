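Package: fertscreen
Title: Genetic and Functional Workup of Fertilization Failure After ICSI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for the diagnostic workup of total or low
    fertilization after intracytoplasmic sperm injection (ICSI). Implements the
    ClinGen naturally scaled points-based Bayesian framework for ACMG/AMP variant
    classification (posterior probabilities, five-tier categories, VUS temperature
    tiers, re-classification after functional evidence), rarity and in-silico
    annotation filters for candidate variant tables, spike detection and amplitude
    x frequency (AxF) scoring of Fura-2 calcium traces from sperm-injected oocytes
    (MOCA/HOCA assays), mouse oocyte activation test (MOAT) grouping, pooled
    clinical-outcome rates with exact two-sided Fisher comparisons of ICSI versus
    ICSI with assisted oocyte activation, sperm acrosome phenotype rates, and
    seeded synthetic-data generators so the full pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
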