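Package: vehitox
Title: Vehicle Effects on Compound Toxicity from Dose-Survival Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding which of two dosing vehicles renders a
    compound less toxic in rodent dose-survival screens. Aggregates
    replicate experiments into mean dose-survival curves, compares
    vehicles by trapezoidal area under the curve with three
    interpolation/extrapolation strategies, rolls per-condition outcomes
    up to compound-level labels, trains decision-tree, random-forest and
    partial-least-squares classifiers on molecular descriptors under
    stratified cross-validation, validates them by y-randomisation
    (ECDF percentile, histogram overlap and exceedance-probability
    criteria), and orders vehicles within substructure-defined compound
    clusters. Includes a synthetic dose-survival generator with known
    ground-truth vehicle effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    rpart,
    randomForest,
    mixOmics,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
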