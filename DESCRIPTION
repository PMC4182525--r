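Package: rnadock
Title: Protein-RNA Rigid-Body Docking Scoring and Weight Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-level scoring of rigid-body protein-RNA docking decoys:
    a coarse-grained (backbone + centroid) stage with contact, bump,
    environment and pair statistical terms, and an all-atom stage with
    Lennard-Jones, Coulomb, Lazaridis-Karplus solvation, 10-12 hydrogen-bond
    and statistical pair terms. Includes a perturbation decoy generator with
    interface-RMSD labelling, a ROC-AUC-maximizing genetic algorithm for
    box-constrained weight optimization through a logistic score, grouped
    leave-one-structure-out cross-validation, and assessment statistics
    (ROC/AUC, top-k precision, enrichment score). Synthetic protein-RNA
    fixture generators make the whole pipeline testable without external
    structure databases.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
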