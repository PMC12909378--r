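Package: ToxScreenMS
Title: Toxicity-Based Prioritization of LC/HRMS Features from Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Flags potentially endocrine-disrupting LC/HRMS features before
    structural identification. Implements spectral-similarity molecular
    networking with activity-label voting (greedy and modified cosine,
    Tanimoto fingerprint networks), modified ROC metrics that penalize
    network-unconnected compounds, Mondrian inductive conformal
    classification on spectral-similarity feature vectors, a
    fingerprint-based gradient-boosted activity classifier with feature
    cleaning, and wastewater influent/effluent feature-fate prioritization
    with multi-approach consensus. A seeded synthetic-data generator
    emulates compounds with hidden toxicophore substructures, spectra
    correlated with fingerprints, and feature intensity tables so the whole
    workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    caret,
    randomForest,
    xgboost,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
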