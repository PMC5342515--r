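Package: oriforest
Title: Replication-Origin Prediction from Dinucleotide Physicochemical
    Pseudo Nucleotide Composition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies origins of replication (ORIs) in human DNA from
    sequence alone. Fixed-length windows are encoded as type-1 pseudo
    k-tuple nucleotide composition (PseKNC) vectors that combine local
    k-mer frequencies with lambda tiers of long-range autocorrelation in
    six dinucleotide physicochemical properties (twist, tilt, roll,
    shift, slide, rise), and classified with a seeded random forest.
    Includes jackknife and stratified K-fold cross-validation with the
    intuitive sensitivity/specificity/accuracy/MCC metrics and ROC/AUC,
    grid search over the encoding parameters (k, lambda, w), a
    sliding-window scanner for long queries with BED output, and a
    first-order Markov generator of labelled synthetic benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
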