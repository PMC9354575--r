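Package: virtualarray
Title: Benchmarking Normalization and Classification for Paired
    Microarray Studies by Virtual Re-Hybridization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates paired microRNA microarray datasets by "virtual
    re-hybridization": per-sample biological effects (virtual samples)
    estimated from a uniformly handled dataset are recombined with
    per-array handling effects (virtual arrays) estimated as paired
    differences against a dataset processed in collection order.
    Arrays are reassigned to samples under confounded, balanced, or
    completely random designs, and the resulting data are pushed
    through a grid of training/test normalization strategies (median,
    quantile, and variance-stabilizing, each alone or frozen toward
    the training reference, plus pooled quantile), seven classifiers
    (nearest shrunken centroids, lasso-penalized logistic regression,
    class-specific nearest centroids, diagonal linear discriminant
    analysis, k-nearest neighbors, random forest, and support vector
    machine), and three validation targets, to measure how these
    choices jointly affect sample misclassification.  A seeded
    synthetic-fixture generator reproduces the paired-study structure
    so the whole pipeline is testable without the original arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    dplyr,
    e1071,
    ggplot2,
    glmnet,
    randomForest,
    rlang,
    stats,
    utils
Suggests:
    limma,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
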