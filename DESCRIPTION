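Package: fadpred
Title: Sequence-Based Prediction of FAD-Interacting Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts flavin adenine dinucleotide (FAD) interacting residues
    in flavoproteins from primary sequence. Implements the FADPred approach:
    odd-length sliding-window patterns around each residue, one-hot (binary)
    and PSI-BLAST PSSM-profile feature encodings, kernel support vector
    machine classification with a positive-class cost factor, and a
    threshold-swept five-fold cross-validation protocol reporting
    sensitivity, specificity, accuracy, Matthews correlation coefficient and
    ROC AUC. Includes readers and writers for case-annotated FASTA (lowercase
    residues mark interacting positions) and PSI-BLAST ASCII PSSM files, a
    seeded synthetic-data generator with plantable compositional and
    profile-conservation signal, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
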