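Package: ruleOmics
Title: Gene-Level Integration of DNA Methylation and RNA-Seq with
    Rule-Based Model Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates DNA methylation and RNA sequencing experiments at
    the gene level for supervised knowledge extraction on tumor cohorts.
    Site-level methylation beta values are aggregated into a per-gene
    methylation quantity (the sum of beta values over the CpG sites
    annotated to the gene), per-experiment sample-by-gene matrices are
    combined by a full outer join on truncated sample barcodes with
    experiment-suffixed feature namespaces, and an ordered threshold-rule
    classifier (RIPPER-style sequential covering with reduced-error
    pruning) is iterated CAMUR-style to enumerate many alternative
    rule-based models by eliminating previously used features.
    Includes stratified cross-validation, grid-search parameter tuning,
    permutation-label validation, gene-set intersection analysis, and a
    synthetic TCGA-like cohort generator with planted class-discriminative
    genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
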