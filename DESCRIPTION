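Package: netstab
Title: Robustness of Graph Community Structure Under Edge Rewiring
Version: 0.1.0
Authors@R:
    person("netstab", "developers", email = "netstab@example.org",
           role = c("aut", "cre"))
Description: Quantifies how robust the community structure of an undirected
    graph is by rewiring a growing fraction of its edges, re-detecting
    communities, and tracking the distance between the reference partition
    and the perturbed partitions. Supports comparison of community-detection
    algorithms and parameter settings via stability curves and their area
    under the curve, validation of detected communities against
    configuration-model null graphs using a Gaussian-process Bayes factor
    and an interval-wise permutation test on functional curves, and the
    construction of KNN/SNN-Jaccard cell graphs from reduced-dimensional
    single-cell embeddings. Includes synthetic generators (stochastic block
    model, Erdos-Renyi, Gaussian-mixture embeddings) so the whole workflow
    is testable without external data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph (>= 1.3),
    Matrix,
    jsonlite,
    methods,
    parallel,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
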