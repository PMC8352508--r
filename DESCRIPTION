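Package: decoygen
Title: Property-Matched Decoy Generation and Bias Assessment for Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building property-matched decoy sets for structure-based
    virtual screening benchmarks. Implements a heavy-atom molecular graph model
    with SMILES/SDF input and output, configurable physicochemical property
    registries (including a synthetic accessibility score), circular structural
    and functional fingerprints with Tanimoto similarity, construction of
    training pairs of structurally dissimilar but property-similar molecules,
    a graph-to-graph variational generative model trained with a
    subgraph-frequency-reweighted action loss, iterative candidate filtering
    with greedy decoy selection, and a bias assessment suite (deviation from
    optimal embedding, doppelganger score, asymmetric validation embedding,
    and machine-learning separability over property subsets).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
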