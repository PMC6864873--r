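Package: ddipass
Title: Severity Prediction of Drug-Drug Interactions from Paired
    Structural Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the clinical severity of drug-drug interactions
    (DDIs) from chemical structure alone. Each drug pair is described by
    PoSMNA descriptors -- the cross product of the two molecules'
    Multilevel Neighbourhoods of Atoms (MNA) substructure strings -- and a
    PASS-style naive Bayes classifier scores the pair against the five
    ORCA severity classes (contraindicated through no interaction),
    reporting rank-calibrated Pa/Pi probabilities per class. Includes MDL
    MOL/SDF input, compound-out leave-one-out and stratified k-fold
    cross-validation scored by IAP (AUC), dataset summaries, and a
    deterministic synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
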