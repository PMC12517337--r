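Package: fedvariant
Title: Cross-Silo Federated Learning Simulation for Variant Pathogenicity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: In-process simulation of cross-silo horizontal federated learning
    for the binary pathogenicity classification of genetic variants. Provides a
    synthetic multi-silo cohort generator emulating submitter-attributed variant
    collections (skewed silo sizes, 1:1 class balance, temporal train/test
    splits, controllable per-silo feature shift), fixed 60-dimensional SNV and
    38-dimensional deletion-CNV feature encodings, two differentiable
    classifiers (a three-layer multilayer perceptron with optional batch
    normalization and a shallow neural decision forest) trained by hand-written
    backpropagation, four federated aggregation algorithms (FedAvg/FedProx and
    the adaptive FedAdagrad/FedAdam/FedYogi family), and the evaluation battery
    of the underlying study: leave-one-chromosome-out folds, collaborative
    cross-validation, AUC-ROC over seed repeats, client-dropout robustness,
    an IID-partition null with z-scores, and hyperparameter grid enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
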