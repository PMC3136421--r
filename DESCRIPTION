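Package: grnbench
Title: Mutual-Information Gene Network Inference and Ensemble Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers undirected gene regulatory networks from expression data
    with mutual-information methods (C3NET maximum-MI selection, relevance
    networks, ARACNE's data processing inequality, MRNET's
    maximum-relevance/minimum-redundancy greedy search) and provides the
    laboratory needed to study them: synthetic directed network generators
    (DAG, scale-free, random, subnetwork sampling), a Hill-kinetics
    steady-state expression simulator with lognormal noise and per-dataset
    kinetic resampling, a copula-based Gaussian mutual-information estimator
    with permutation significance testing, and global (precision, recall,
    F-score, optimal cut-off) plus local (edge true-positive rates,
    activator/repressor contrasts, degree-sum ANOVA, three-node motif
    reconstruction) performance metrics over dataset ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
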