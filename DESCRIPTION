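Package: ymazer
Title: Y-Maze Phenotyping of Zebrafish Locomotion with Probit Toxicology
    and Track-Image Classification
Version: 0.1.0
Authors@R:
    person("Track", "Phenotyping Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for dose-response behavioural
    phenotyping of adult zebrafish in the aquatic Y-maze. Scores
    spontaneous alternation behaviour (SAB) and locomotor endpoints from
    positional track tables, estimates LD50 from dose-group mortality by
    the Miller-Tainter probit regression with Abbott control correction,
    rasterizes 30-second track segments to grayscale images and trains a
    small residual convolutional network to predict day-by-dose class,
    benchmarks observed accuracy against a label-permutation baseline,
    and clusters the resulting confusion matrix as a weighted similarity
    graph with Louvain modularity optimization. A synthetic-data module
    generates trajectories, mortality tables and inhibitory-avoidance
    latencies with planted, parameterized group effects so that every
    stage of the pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
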