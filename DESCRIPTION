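Package: readnet
Title: Graph-Theoretic Analysis of Task-Based Reading-Network Connectivity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds binary functional-connectivity graphs from node-level fMRI
    time series under two thresholding schemes (uncorrected significance of the
    Pearson correlation, and the minimum connected component), quantifies
    network segregation (modularity, transitivity) and integration (global
    efficiency) per participant and presentation modality, and predicts reading
    skill (pseudo-word decoding efficiency) with a hierarchical regression plus
    an exact LMG relative-importance decomposition with bootstrap contrasts.
    Includes a synthetic-cohort generator with planted modular covariance so the
    full pipeline is testable without access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
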