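Package: pseudoU
Title: Pseudouridine Site Prediction from RNA Sequence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts pseudouridine (Psi) sites in RNA sequences with a
    radial-basis-function support vector machine trained on five sequence
    feature encodings: nucleotide composition, dinucleotide composition,
    pseudo dinucleotide composition, and position-specific nucleotide and
    dinucleotide propensity matrices fitted as frequency differences between
    validated and non-validated uridine segments. Includes a leakage-safe
    leave-one-out (jackknife) evaluation protocol that refits the propensity
    matrices inside every fold, grid search over the SVM box constraint and
    kernel scale, greedy sequential forward feature selection, Chou's
    sensitivity/specificity/accuracy/MCC metrics with ROC/AUC, a sliding
    window scanner with mirror-image padding for query sequences, and a
    synthetic benchmark generator with planted position-specific signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
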