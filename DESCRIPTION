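Package: pancut
Title: Assisted Clustering of Gene Expression with Partially Overlapping
    Regulatory Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters gene-expression profiles with the help of upstream
    regulatory measurements (for example DNA methylation beta values)
    collected on a different but partially overlapping set of individuals.
    Per-gene elastic-net regressions fitted on the overlapping individuals
    predict the regulated component of expression; observed and predicted
    similarity matrices then drive a graph-cut objective (between-cluster
    over within-cluster similarity) minimised by simulated annealing.
    Includes silhouette and elbow selection of the number of clusters,
    full-overlap and overlap-only comparator modes, a K-means baseline,
    adjacency-matrix accuracy metrics, and generators for two synthetic
    benchmark scenarios with block-structured regulators, sparse
    regulator-to-gene transition matrices and structured error covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
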