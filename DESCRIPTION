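Package: commfit
Title: Supervised Overlapping Community Detection on Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects overlapping communities (e.g. protein complexes) in
    weighted interaction networks by learning a community fitness function
    from known communities as a binary classifier over 18-dimensional
    topological embeddings, growing seed nodes into candidate communities
    with epsilon-greedy heuristics optionally combined with iterative
    simulated annealing or pseudo-metropolis acceptance, merging overlapping
    candidates by fitness, and scoring learned against known community sets
    with matching-based evaluation measures (maximum-weight bipartite
    F-similarity matching, community-wise maximum F-similarity, unbiased
    sensitivity/positive-predictive-value accuracy) alongside legacy
    measures. Includes generators for planted-community benchmark networks
    and end-to-end pipeline orchestration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    parallel,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
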