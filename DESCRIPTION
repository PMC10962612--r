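Package: mNFE
Title: Single-Sample Network Flow Entropy for Tipping-Point Detection in
    Longitudinal Microbiome Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects pre-disease (tipping-point) states in longitudinal
    taxon-abundance profiles on a single-sample basis. A sparse microbial
    association network is inferred from reference samples by neighborhood
    selection (MB) on centered log-ratio transformed abundances; adding one
    case sample yields a sample-specific association network, and the change
    in network flow entropy (NFE) averaged over local (center plus
    first-order neighbor) networks gives a per-time-point mNFE score.
    Sharp increases of the score flag critical states, the top-scoring taxa
    form dynamic network biomarkers (DNBs), and companion tools cover alpha
    and beta diversity baselines, differential-abundance screening for
    "dark species", network connectivity and fragility curves, an eight-node
    regulatory-network simulator with a programmed bifurcation, and a
    synthetic longitudinal cohort generator with programmed DNB structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    glmnet,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Microbiome, Network, TimeCourse, GraphAndNetwork, Metagenomics
RoxygenNote: 7.3.3
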