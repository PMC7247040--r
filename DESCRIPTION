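Package: conparc
Title: Consensus Connectivity-Driven Brain Parcellation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectivity-driven cortical parcellation from dense
    vertex-resolution connectomes. Individual connectomes are clustered by
    three-level hierarchical Louvain modularity maximization and aggregated
    into a consensus parcellation by the hard-ensemble algorithm, a greedy
    pseudo-Karcher mean under a label-permutation-invariant partition
    distance. Includes CSPA and average-graph consensus baselines, an
    evaluation suite (Kullback-Leibler fidelity of the piecewise-constant
    connectome approximation, adjusted mutual information with the
    hypergeometric permutation-model correction, minimal-cover Dice overlap,
    hemispheric symmetry, spatial contiguity, weighted graph characteristics,
    an L1-logistic classification harness), and a synthetic cohort generator
    on subdivided icosahedral sphere meshes with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
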