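Package: chemodissect
Title: Dissecting Selectivity Determinants at Chemokine-Receptor Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analyzing how selectivity and promiscuity are encoded
    in the chemokine ligand-receptor family. Implements common residue
    numbering for chemokines (CCN) and chemokine GPCRs (CRN) with
    anchor-cysteine stacking conventions, trident-style per-position
    conservation scoring, per-position CC-versus-CXC logistic-regression
    subfamily scoring and prediction probabilities for query sequences,
    inter-chain residue contact detection and contact fingerprinting with
    conserved/consensus/preserved-variable filters, receptor-anchored
    structural superposition with per-position Calpha deviations,
    alignment-free short linear motif (SLiM) discovery by ortholog
    conservation, variant and deep-mutational-scan summarization, and
    literature interaction-network analysis. A synthetic-data generator
    produces fixtures with known ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
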