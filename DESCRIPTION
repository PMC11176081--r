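Package: stoichsi
Title: Stoichiometric Imbalance Analysis of Case-Control Brain Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies stoichiometric imbalance (SI) in gene expression for
    case-control bulk RNA-seq cohorts. Each gene in a GWAS-derived set is
    modelled as a penalised (LASSO) linear function of the other genes plus
    known covariates, fitted on resampled control subsets; weighted scaled
    residuals are averaged across resampling iterations, standardised against
    healthy controls, and aggregated into a per-individual SI score.
    Includes TMM/RPKM normalisation and covariate residualisation, locus-to-gene
    prioritisation of candidate genes, rank-based differential expression with
    Benjamini-Hochberg correction, cross-cohort logistic classification with
    liability-scale Nagelkerke R-squared, polygenicity summaries of imbalanced
    genes, and a multi-cohort synthetic-data generator with ground-truth
    perturbation labels for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    edgeR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
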