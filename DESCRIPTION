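Package: MethylCascade
Title: Knockout-Guided Integrative Methylome-Transcriptome Candidate Gene
    Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an end-to-end candidate-gene discovery pipeline that
    integrates differential DNA methylation from capture sequencing and
    negative-binomial differential expression in knockout versus parental
    cell lines with cohort-level concordance filtering, rank-based
    clinicopathological association testing, ROC and logistic-regression
    classification of tumor status, outcome-driven survival cutpoint
    optimization, and MethyLight delta-delta-Ct quantification. Ships a
    synthetic-data generator with planted driver genes so the full cascade
    is testable without external cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, DifferentialExpression, DifferentialMethylation,
    Epigenetics, Survival, Classification
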