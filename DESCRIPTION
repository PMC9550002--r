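Package: septree
Title: Tree-Stratified Two-Stage Risk-Factor Analysis for Postoperative Sepsis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of putative risk factors for a binary clinical
    outcome in the presence of many categorical confounders. Stage one grows a
    recursive-partitioning (CART-style) tree on confounders only, using the
    between-group sum-of-squares split criterion, cost-complexity pruning with
    stratified k-fold cross-validation, and AIC selection among nested
    confounder sets; the pruned leaves define homogeneous-risk strata. Stage
    two estimates crude and Mantel-Haenszel stratum-adjusted odds and risk
    ratios for each putative risk factor across the tree strata, with a
    logistic-regression sensitivity analysis including interaction screening
    and forward-stepwise selection. A synthetic-cohort generator with a
    planted tree-structured risk mechanism supports end-to-end testing and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), rpart, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
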