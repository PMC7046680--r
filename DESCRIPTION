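Package: lcmROC
Title: Bayesian Latent Class Estimation of Diagnostic Accuracy Without a
    Gold Standard
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates sensitivity, specificity, AUC, Youden-optimal
    cut-offs and optimal linear marker combinations for continuous
    diagnostic markers when no gold-standard disease label exists.
    Disease status is treated as a two-class latent variable; single-marker
    binormal and covariate-adjusted multivariate-normal latent class models
    are fitted by Markov chain Monte Carlo with conjugate Gibbs updates and
    an adaptive Metropolis step for the logistic prevalence model. Includes
    closed-form binormal receiver operating characteristic machinery, a
    distributional overlap separation measure, Geweke and autocorrelation
    convergence diagnostics, a synthetic transplant-cohort generator and a
    pipeline reproducing the full analysis workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
biocViews: Bayesian, Classification, StatisticalMethod
RoxygenNote: 7.3.3
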