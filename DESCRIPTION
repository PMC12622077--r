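Package: BloodBiasAudit
Title: Bias Auditing and Multimodal Classification for Case-Control Blood
    Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing systematic bias in case/control blood
    expression matrices and for building matched, multimodal disease
    classifiers. Quantifies dataset-level bias through the classification
    performance of randomly sampled gene sets under leave-one-out
    cross-validation, estimates white-blood-cell composition by
    non-negative least-squares deconvolution, removes plate and site
    effects by supervised empirical-Bayes location-scale adjustment and
    continuous-covariate residualisation, and runs a propensity-matched,
    ensemble-mRMR, concatenation-fusion classification protocol with
    sex-stratified metrics and permutation-sampled Shapley importance.
    A synthetic-cohort generator reproduces the statistical structure the
    analysis assumes (cell-type mixtures, plate/site batches, sex-specific
    effects, technical replicates, an MRI-like feature block) so the whole
    chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    e1071,
    randomForest,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
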