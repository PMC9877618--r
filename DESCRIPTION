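Package: ProtStress
Title: Abiotic-Stress Protein Sequence Classification with the SIELU Activation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for binary classification of abiotic-stress-responsive protein
    sequences (cold, drought, heat, salt) from sequence-derived features. Implements the
    SIELU activation function (the tanh-form GELU rewritten through the sigmoid identity)
    together with the classical normal-distribution approximations it descends from, a
    46-feature protein sequence encoder (residue composition, physicochemical indices,
    post-translational-modification motif counts, coiled-coil score), greedy identity-based
    redundancy removal, stratified splitting and scaling, a small feed-forward/one-step
    recurrent neural classifier with SVM and random-forest baselines, confusion-matrix
    metrics with PR/ROC curves, a synthetic two-class sequence generator, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
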