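Package: nadbinder
Title: Sequence-Based Prediction of NAD-Interacting Residues in Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts nicotinamide adenine dinucleotide (NAD) interacting
    residues (NIRs) in proteins from amino-acid sequence alone. Residues are
    encoded as fixed-length sliding-window features, either one-hot binary
    profiles over a 21-letter alphabet or evolutionary profiles taken from
    position-specific scoring matrices (PSSMs), and classified with a kernel
    support vector machine. The package also derives per-residue contact
    labels from protein-NAD complex structures with a side-chain distance
    criterion, reduces sequence redundancy by greedy identity clustering,
    evaluates models by chain-level five-fold cross-validation (sensitivity,
    specificity, accuracy, Matthews correlation coefficient, ROC/AUC),
    aggregates residue predictions into protein-level NAD-binder calls, and
    ships a synthetic-data generator (motif-planted sequences, pseudo-PSSMs,
    toy complexes) so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
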