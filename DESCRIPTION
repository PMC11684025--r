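Package: kindock
Title: Docking-Informed Kinome-Wide Binding Affinity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation, docking-pose management and machine-learned rescoring
    for kinase inhibitor affinity prediction. Implements drug-likeness and
    structure-quality curation of kinase bioactivity data, a van der Waals
    overlap clash score with a data-driven 3-sigma acceptance threshold for
    docked poses, ECFP and protein-ligand extended connectivity (PLEC) bit
    fingerprints, a 3-layer neural scoring network with leakage-aware
    random/compound/kinase splits and best-checkpoint selection, flat-mean
    aggregation of per-pose predictions into a single affinity estimate, and
    an SQLite pose database, together with deterministic synthetic fixtures
    (toy complexes, planted structure-activity data) for testing at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    DBI,
    RSQLite,
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
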