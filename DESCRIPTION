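Package: targetrank
Title: Drug-Target Prediction from Perturbation Signature Correlations
Version: 0.1.0
Authors@R:
    person("targetrank", "developers", email = "targetrank@localhost",
           role = c("aut", "cre"))
Description: Predicts protein targets of small molecules from L1000-style
    differential-expression compendia. Drug-treatment signatures are compared
    with gene-knockdown signatures across cell lines to derive direct and
    indirect (protein-interaction-partner) correlation features, cell-activity
    and partner differential-expression features, which are combined by
    random-forest rankers (a pooled two-level architecture and per-drug
    on-the-fly models) under leave-one-out cross-validation. Genomic rankings
    can be re-ranked with externally supplied docking scores. Includes a
    seeded synthetic-compendium generator with planted direct and indirect
    drug-target structure, a published 29-drug validation benchmark, and
    rank-based evaluation utilities (top-k accuracy, normalized-rank ROC/AUC,
    permutation baselines, hypergeometric enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
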