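Package: SeqMomentStack
Title: Carcinogenic Mutation Classification from Gene Sequences via
    Statistical-Moment Features and a Stacked Recurrent Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds balanced normal/mutated gene-sequence corpora by applying
    driver-mutation tables to reference sequences, extracts a 522-component
    descriptor per sequence (k-mer frequency vectors, accumulative position
    incidence vectors, position-relative incidence matrices, and raw, central
    and discrete Hahn moments over single-, bi- and tri-nucleotide
    configurations), trains a stacked ensemble of three gated recurrent
    networks (LSTM, GRU, bidirectional LSTM) with a logistic-regression
    meta-learner, and evaluates binary classifiers under self-consistency,
    independent-set and 10-fold cross-validation protocols with a full
    confusion-matrix metric panel (accuracy, precision, recall, sensitivity,
    specificity, F1, MCC, Cohen's kappa, ROC/AUC). Ships a deterministic
    synthetic corpus generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
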