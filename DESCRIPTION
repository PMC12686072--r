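Package: ehbmt
Title: EMT-Heterogeneity-Based Molecular Typing of Bulk Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies bulk gene-expression cohorts into epithelial (EPC),
    hybrid (HPC) and mesenchymal (MPC) phenotype clusters by unsupervised
    complete-linkage clustering on a fixed epithelial/mesenchymal marker
    panel with Pearson-correlation distance, and provides the downstream
    statistics used to characterise such subtypes: contingency-table
    association tests against clinical covariates, paired normal-to-tumor
    subtype transition (traceability) analysis with Sankey export,
    Kaplan-Meier and log-rank survival comparison, rank-based single-sample
    enrichment scores for label verification, single-cell E/M ratios,
    immunohistochemistry score subtyping, marker correlation-block analysis,
    and a synthetic-cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
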