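Package: mnasar
Title: Substructural MNA Descriptors and Bayesian Structure-Activity
    Prediction for Cell-Line Cytotoxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Atom-centered Multilevel Neighborhoods of Atoms (MNA)
    substructural descriptors computed from SMILES or MDL Molfile/SDF
    structures, a regularized naive-Bayes scorer producing calibrated
    Pa/Pi (probability active / probability inactive) pairs per
    biological activity, analytic leave-one-out and stratified k-fold
    cross-validation with invariant accuracy of prediction (IAP, equal
    to ROC AUC), and curation rules turning raw cytotoxicity and
    mechanism-of-action activity tables into binary labeled sets.
    Includes a synthetic-data generator with planted structure-activity
    signal and a command-line interface covering the full curate, train,
    validate, predict workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
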