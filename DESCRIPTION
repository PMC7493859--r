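Package: nucnet
Title: Hybrid Convolutional-Recurrent Neural Classification of Nucleosome
    and Linker DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies fixed-length DNA sequences (default 147 bp) as
    nucleosome-forming or linker using a hybrid neural network: a shared
    convolutional feature extractor feeding two parallel paths, a
    sequence-output LSTM that captures periodic dinucleotide structure and
    a second convolutional stage that captures localized motifs, merged by
    concatenation into a dense sigmoid classifier. Includes one-hot
    sequence encoding, a seeded synthetic-data generator with plantable
    periodic and motif signals, the full training protocol (Adam, binary
    cross-entropy with L2 weight decay, early stopping on validation
    loss), stratified k-fold cross-validation and bootstrap resampling
    evaluation, and classification metrics (accuracy, sensitivity,
    specificity, Matthews correlation coefficient, ROC AUC). All network
    computation is implemented in base R matrix operations; no GPU or
    external deep-learning runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
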