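Package: metabocross
Title: Metabolomic Fingerprinting of Placebo-Controlled Crossover Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for targeted-metabolomics crossover trials
    of drug intoxication and use frequency. Implements repeated double
    cross-validated partial least squares discriminant analysis (rdCV-PLS-DA)
    with recursive feature elimination ranked by Variable Importance in
    Projection and permutation-test significance; per-metabolite linear mixed
    models of post-dose kinetics with subject random intercepts and AR(1)
    within-series correlation; change-score association models linking
    metabolite shifts to behavioural outcomes; two-level hierarchical
    family-wise false discovery rate control; metabolomics preprocessing
    (ratio features, log transform, Pareto scaling, EM-PCA imputation); and a
    synthetic-study generator that emulates a two-group placebo-controlled
    cannabis crossover design so the whole pipeline is exercisable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
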