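Package: mcart
Title: Covariate-Balanced Treatment-Effect Subgroups via Matching and
    Conditional Inference Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers heterogeneous-treatment-effect (HTE) subgroups in
    two-arm randomized trials with binary outcomes while guarding against
    false discovery driven by covariate imbalance.  Treated and control
    participants are pair-matched on a rank-based Mahalanobis distance by an
    optimal bipartite assignment, pairs disagreeing on categorical covariates
    are discarded, and a conditional inference tree is fitted to the
    pair-level treatment-effect differences.  Discovered subgroups are
    projected back onto the trial to estimate per-subgroup risk differences
    with confidence intervals, absolute standardized differences, and (when
    the truth is known, e.g. in simulation) bias.  Includes a simulator for
    five benchmark randomized-trial designs with known potential outcomes,
    comparator strategies (logistic regression with backward-AIC interaction
    selection and a random-forest adapter), and balance and sample-size
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
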