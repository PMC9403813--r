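Package: hqsar
Title: Hologram QSAR with Ensemble Modelling for Retention-Index Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds hologram quantitative structure-activity relationship
    (HQSAR) models from SMILES structures: enumerates all connected
    molecular fragments within a size window, labels them under a set of
    fragment-distinction flags (atoms, bonds, connections, hydrogens,
    chirality, donor/acceptor), hashes the canonical fragment keys into
    fixed-length integer holograms with a CRC-32 hash, and regresses a
    property on the hologram by partial least squares with leave-one-out
    component selection.  Includes the two-stage fragment-distinction /
    fragment-size hyperparameter search, consensus (ensemble) models built
    as the arithmetic mean of several individual models, a suite of
    external-validation statistics (q2, CCC, QF2, QF3, RMSE, MAPE), a
    synthetic carbonyl-compound generator with a known structure-property
    relationship, and a bundled 34-compound aldehyde/ketone
    gas-chromatography retention-index dataset on two stationary phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
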