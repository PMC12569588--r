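Package: ppmcc
Title: Bias-Aware Evaluation of Protein-Protein Interaction Classifiers
Version: 0.1.0
Authors@R:
    person("ppmcc", "developers", email = "ppmcc@example.org", role = c("aut", "cre"))
Description: Evaluation framework for sequence-based protein-protein
    interaction (PPI) classifiers that corrects for per-protein positivity
    bias. Provides the per-protein Matthews correlation coefficient (pp_MCC)
    utility metric with its skip rule and interaction-count weighting, random
    and unseen-protein nested cross-validation splits, a positivity-prior
    baseline, pair-feature combination of protein embeddings, classical
    learner families (k-nearest neighbours, penalised logistic regression,
    random forest), and a synthetic generator of interaction datasets with
    controllable per-protein positivity bias for end-to-end testing without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    Biostrings,
    glmnet,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
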