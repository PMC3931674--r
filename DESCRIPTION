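Package: cnaDissim
Title: Dissimilarity-Space Inference of Tumor Stage Progression from
    Integrated Expression and Copy-Number Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates differential gene expression (two-sample rank
    product with permutation-based significance) and recurrent copy-number
    alteration calls across multiple cohorts into per-task gene signatures
    for colorectal-cancer stage progression, represents patients by their
    dissimilarities to a lowest-stage prototype group (Euclidean,
    Manhattan, Kendall tau and symmetrized Kullback-Leibler distances),
    and compares representation criteria by grid-optimized linear support
    vector machine AUC under stratified cross-validation, with chi-squared
    goodness-of-fit evaluation of success/failure profiles. Includes a
    multi-cohort synthetic-data generator with planted ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, CopyNumberVariation, Classification,
    DifferentialExpression, SupportVectorMachine
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
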