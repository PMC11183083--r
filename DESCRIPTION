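Package: batcheval
Title: Multivariate Detection and Effect-Size Quantification of Batch
    Effects in Radiomic Feature Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating batch effects in radiomics-style feature
    matrices. Provides distance-based permutational multivariate analysis of
    variance (PERMANOVA) over six dissimilarity metrics for dataset-level
    screening, the Robust Effect Size Index (RESI) with bootstrap confidence
    intervals for feature-level quantification, univariate comparator tests
    (Wilcoxon rank-sum, Kolmogorov-Smirnov, k-sample Anderson-Darling),
    parametric empirical-Bayes location/scale harmonization (ComBat) with
    covariate protection, a simulator of location/scale batch effects, and a
    power/Type-I-error study harness. Feature data are carried in a
    BatchExperiment container extending SummarizedExperiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    knitr,
    rmarkdown
biocViews: BatchEffect, StatisticalMethod, Normalization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
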