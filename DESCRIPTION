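Package: vervetIGC
Title: Non-Adult Participation in Vervet Monkey Intergroup Conflict
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for studying how infant and juvenile vervet
    monkeys come to take part in aggressive intergroup conflict (IGC).
    Provides a synthetic cohort generator emulating scan sampling, agonistic
    observations and IGC event records; annual grooming and spatial
    association networks with eigenvector centrality; sequential Elo ratings
    with date-indexed rank lookup; Bayesian mixed models for participation
    (Bernoulli), aggression intensity (cumulative ordinal with a monotonic
    maternal-aggression predictor) and within-IGC grooming, including a
    nested double-hurdle model of grooming receipt and maternal grooming;
    plus posterior diagnostics (split R-hat, probability of direction,
    Bayesian R-squared, ROC/AUC, residual autocorrelation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    lme4,
    rjags,
    optparse,
    knitr
Config/testthat/edition: 3
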