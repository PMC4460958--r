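Package: pmfrepurpose
Title: Drug Repurposing by Ensemble Probabilistic Matrix Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Infers repurposable drugs for a query protein target from a
    sparse binary drug-target interaction network. Probabilistic matrix
    factorization is repeated under many seeds and each run's top-k
    predictions for the target are pooled; drug latent vectors are then
    clustered agglomeratively under several distance metrics, clusters
    enriched in known ligands (one-sided hypergeometric test with
    Benjamini-Hochberg correction) are intersected across metrics, and the
    consensus candidates are filtered by a two-component fingerprint combo
    score against a chemical reference panel expanded around the known
    ligands. Includes a planted-structure synthetic-data generator so the
    whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
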