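Package: immunoCYT
Title: Cytolytic Activity Stratification and Immunogenomic Association
    Analysis for Colorectal Tumor Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stratifies bulk RNA-seq tumor cohorts by an immune cytolytic
    index (the geometric mean of GZMA and PRF1 expression on the TPM scale)
    and associates the resulting CYT-high and CYT-low strata with somatic
    mutation burden, microsatellite instability called from mismatch-repair
    gene mutations, mutant-allele tumor heterogeneity (MATH), copy-number
    event burden from segment means, classically and alternatively defined
    neoepitope loads with the differential agretopicity index, immune
    checkpoint expression, Kaplan-Meier survival with two-gene synergy
    groups, and histology-derived ordinal scores. Includes a seeded
    synthetic cohort generator with planted, recoverable effects so the
    full pipeline can be exercised and power-checked without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
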