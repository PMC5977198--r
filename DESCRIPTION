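Package: entroSelect
Title: Ensemble Filter and Cross-Entropy Based Gene Selection for
    Two-Class Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects small, non-redundant, highly discriminative gene
    subsets from two-class expression matrices. Genes are first ranked by
    three univariate filters (signal-to-noise ratio, two-sample
    t-statistic, Pearson correlation with the class), the per-filter
    top-N lists are merged into a candidate set, redundant candidates
    are removed with a normalized cross-entropy (total correlation)
    screen on discretized expression, and a greedy forward wrapper
    scored by stratified cross-validated classification accuracy (KNN,
    linear SVM or naive Bayes) picks the final subset. Includes a
    seeded generator of microarray-like synthetic data with known
    informative, redundant and noise genes, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, class, e1071, jsonlite, yaml,
    optparse
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, GeneExpression, Microarray
RoxygenNote: 7.3.3
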