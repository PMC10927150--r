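Package: top2tox
Title: Cardiotoxic Response Signatures of Topoisomerase II Inhibitors in
    iPSC-Derived Cardiomyocytes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for characterising the cardiomyocyte
    response to topoisomerase-II-inhibiting cancer drugs from in vitro
    assays: four-parameter log-logistic dose-response modelling with a
    fixed upper asymptote and LD50 extraction, calcium-transient feature
    extraction from fluorescence recordings, moderated differential
    expression with precision weights, a joint correlation-motif EM
    mixture model over all drug-by-time contrasts with BIC/AIC motif
    selection and response-signature labelling, inter-individual
    expression variance analysis, and gene-set / GWAS-locus annotation.
    Includes a synthetic-data generator that emulates the multi-donor,
    multi-drug, two-timepoint study design so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    limma,
    edgeR,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneExpression, DifferentialExpression, RNASeq, Software,
    Bayesian, Clustering, Pharmacogenomics
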