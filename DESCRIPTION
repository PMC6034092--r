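Package: groupRF
Title: Group-Level Random Forest Importance Scores and Permutation-Based
    Group Selection
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes Mean Decrease of Impurity (MDI) feature importances
    from Random Forests classifiers and aggregates them over predefined
    disjoint feature groups (for example brain-atlas regions) with sum,
    average or max aggregation. Converts group-importance rankings into
    statistically interpretable scores with four permutation-based
    procedures: the conditional error rate (CER), its rank-based variant
    (CER^r), a permutation estimate of the false discovery rate (eFDR),
    and the random-probes FWER estimate (mProbes). Includes a synthetic
    linear benchmark generator with known relevant groups, precision /
    recall / AUPR ranking metrics, and construction of feature partitions
    from NIfTI atlas label volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
RoxygenNote: 7.3.3
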