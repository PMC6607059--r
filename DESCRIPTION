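Package: phenotrial
Title: Variance Components, Stress Indices and Stability Analysis for
    Multi-Treatment Plant Phenotyping Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for balanced multi-treatment plant phenotyping
    trials (genotype x treatment x replicate trait tables), built around a
    synthetic-trial generator so every stage is testable without deposited
    data. Provides REML and method-of-moments estimation of genotype,
    genotype-by-treatment and (possibly treatment-heterogeneous) residual
    variance components with AIC model selection, likelihood-ratio tests,
    broad-sense heritability and genotype BLUPs; descriptive trait summaries
    and Pearson correlation networks on BLUPs; ridge and lasso trait
    selection against biomass with fivefold cross-validation; stress
    tolerance indices (SSI, TOL, MP, GMP, STI), 10-grade scoring, RCI/PCI
    aggregation and Fernandez A-D genotype classification with Welch group
    comparisons; and AMMI stability analysis of the genotype-by-treatment
    table via double-centering and singular value decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
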