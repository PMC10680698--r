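Package: vlseval
Title: Retrospective Virtual Ligand Screening Evaluation for GPCR Antagonists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating retrospective virtual ligand
    screening (VLS) campaigns against G-protein-coupled receptor binding
    pockets. Covers compound library curation (pActivity conversion,
    threshold-based active/inactive role assignment, circular-fingerprint
    chemotype clustering by UPGMA on Tanimoto distances), property-matched
    decoy selection, two-stage pose-selection/compound-ranking scoring
    schemes over single receptor models and pooled conformer ensembles,
    ROC/AUC and early-enrichment metrics, activity-cliff detection,
    receptor geometry analysis with Ballesteros-Weinstein annotations
    (backbone superposition, inter-residue distance tables, ligand
    envelope sampling boxes, mutation-reversion bookkeeping), declarative
    induced-fit fragment and restraint specifications, and a seeded
    synthetic-data generator that emulates chemotype-by-conformer induced
    fit so that every pipeline stage is testable without proprietary
    docking output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
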