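#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom Rcpp sourceCpp
#' @useDynLib BloodBiasAudit, .registration = TRUE
NULL

#' Cell-type reference signature matrix
#'
#' Linear-scale reference expression for a panel of cell types, genes in rows
#' and cell types in columns, together with the marker genes planted for each
#' type. Used as the reference for non-negative least-squares deconvolution
#' and as the mixing basis of the synthetic-cohort generator.
#'
#' @slot values non-negative numeric matrix, genes x cell types, with dimnames.
#' @slot markerMap named list mapping each cell type to its marker gene ids.
#'
#' @seealso [generateSignatureMatrix()], [estimateFractions()]
#' @export
setClass("SignatureMatrix",
  representation(values = "matrix", markerMap = "list"))

setValidity("SignatureMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (any(v < 0)) msg <- c(msg, "signature values must be non-negative")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "signature matrix must carry gene and cell-type dimnames")
  if (!setequal(names(object@markerMap), colnames(v)))
    msg <- c(msg, "markerMap names must match cell-type columns")
  if (qr(v)$rank < ncol(v))
    msg <- c(msg, "signature columns must be linearly independent")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort configuration
#'
#' All tunable parameters of the synthetic-cohort generator. Defaults describe
#' the standard confounded whole-blood cohort: a 50/50 case-control design of
#' 346 subjects on 18 plates across 3 sites, a Dirichlet cell mixture whose
#' neutrophil fraction is shifted upwards in cases, plate assignment mildly
#' associated with diagnosis, a planted log2 disease effect partly restricted
#' to one sex, technical replicates with technical noise below biological
#' noise, and an MRI-like block coupled to a latent severity variable.
#'
#' @slot nSubjects number of subjects.
#' @slot caseFraction,femaleFraction proportions of cases and of females.
#' @slot nGenes,nCellTypes feature-space and mixture dimensions.
#' @slot dirichletBase Dirichlet concentration vector (first entry is the
#'   neutrophil component).
#' @slot neutrophilShift additive shift of the mean neutrophil fraction in
#'   cases (on the proportion scale).
#' @slot nPlates,nSites numbers of plate and site batches.
#' @slot plateCaseAssoc strength in `[0,1)` of the association between plate
#'   assignment and diagnosis (0 = independent).
#' @slot plateLocationSd,plateScaleSd per-gene per-plate location-offset sd
#'   and log-scale-factor sd. Site offsets use half the plate location sd.
#' @slot nDeGenes,deEffectLog2 number of planted disease genes and their
#'   absolute log2 effect size.
#' @slot sexSpecificFraction fraction of planted genes whose effect is active
#'   in one sex only.
#' @slot biologicalSd,technicalSd per-gene subject-level and measurement-level
#'   noise sds (log2 scale).
#' @slot nReplicateSubjects subjects receiving one technical replicate each.
#' @slot mriNFeatures,mriLoading,mriLatentShift MRI block width, loading scale
#'   and case-control shift of the latent severity variable.
#' @slot ageMeanCase,ageMeanControl,ageSd age distribution (years), truncated
#'   to 50-95.
#' @slot seed integer RNG seed; one stream per generator call.
#'
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
  representation(
    nSubjects = "numeric", caseFraction = "numeric",
    femaleFraction = "numeric", nGenes = "numeric", nCellTypes = "numeric",
    dirichletBase = "numeric", neutrophilShift = "numeric",
    nPlates = "numeric", nSites = "numeric", plateCaseAssoc = "numeric",
    plateLocationSd = "numeric", plateScaleSd = "numeric",
    nDeGenes = "numeric", deEffectLog2 = "numeric",
    sexSpecificFraction = "numeric", biologicalSd = "numeric",
    technicalSd = "numeric", nReplicateSubjects = "numeric",
    mriNFeatures = "numeric", mriLoading = "numeric",
    mriLatentShift = "numeric", ageMeanCase = "numeric",
    ageMeanControl = "numeric", ageSd = "numeric", seed = "numeric"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  pr <- c(object@caseFraction, object@femaleFraction,
          object@sexSpecificFraction, object@plateCaseAssoc)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "proportions must lie in [0,1]")
  if (object@neutrophilShift < -1 || object@neutrophilShift > 1)
    msg <- c(msg, "neutrophilShift must lie in [-1,1]")
  if (any(object@dirichletBase <= 0))
    msg <- c(msg, "dirichletBase must be positive")
  if (length(object@dirichletBase) != object@nCellTypes)
    msg <- c(msg, "dirichletBase length must equal nCellTypes")
  if (object@nDeGenes > object@nGenes)
    msg <- c(msg, "nDeGenes cannot exceed nGenes")
  if (any(c(object@biologicalSd, object@technicalSd, object@plateLocationSd,
            object@plateScaleSd, object@ageSd) < 0))
    msg <- c(msg, "noise and batch sds must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort
#'
#' A generated case-control cohort: a log2 expression matrix with per-sample
#' metadata (held in a [SummarizedExperiment::SummarizedExperiment]), the true
#' cell fractions and planted disease genes used to build it, the latent
#' severity variable, and the coupled MRI-like feature block.
#'
#' @slot se SummarizedExperiment; assay `"log2"` holds genes x samples
#'   expression, `colData` the sample metadata (diagnosis, sex, age, plate,
#'   site, subject_id, replicate_group).
#' @slot trueFractions samples x cell types matrix of generating mixtures.
#' @slot trueDeGenes data.frame of planted genes: gene, effect (signed log2),
#'   sex (`"both"`, `"F"` or `"M"`).
#' @slot latentSeverity named numeric, one value per subject.
#' @slot mri subjects x features matrix of MRI-like measurements.
#' @slot config the [CohortConfig-class] that produced the cohort.
#'
#' @seealso [generateCohort()], [exprMatrix()], [sampleInfo()]
#' @export
setClass("SyntheticCohort",
  representation(se = "SummarizedExperiment", trueFractions = "matrix",
                 trueDeGenes = "data.frame", latentSeverity = "numeric",
                 mri = "matrix", config = "CohortConfig"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  rs <- rowSums(object@trueFractions)
  if (any(abs(rs - 1) > 1e-9))
    msg <- c(msg, "true fractions must sum to 1 per sample")
  sm <- colnames(object@se)
  if (!identical(sort(sm), sort(rownames(object@trueFractions))))
    msg <- c(msg, "trueFractions rows must match expression columns")
  md <- SummarizedExperiment::colData(object@se)
  if (anyDuplicated(rownames(md)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Estimated cell-type fractions
#'
#' Output of non-negative least-squares deconvolution: per-sample cell-type
#' proportions plus the absolute immune signal (the sum of unnormalised NNLS
#' coefficients, proportional to total signature-explained signal).
#'
#' @slot fractions samples x cell types matrix; rows sum to 1.
#' @slot absoluteScore named non-negative numeric, one value per sample.
#'
#' @seealso [estimateFractions()], [scaleCovariate()]
#' @export
setClass("CellFractionEstimates",
  representation(fractions = "matrix", absoluteScore = "numeric"))

setValidity("CellFractionEstimates", function(object) {
  msg <- character()
  if (any(abs(rowSums(object@fractions) - 1) > 1e-9))
    msg <- c(msg, "fraction rows must sum to 1")
  if (any(object@absoluteScore < 0))
    msg <- c(msg, "absolute scores must be non-negative")
  if (length(object@absoluteScore) != nrow(object@fractions))
    msg <- c(msg, "one absolute score per sample required")
  if (length(msg)) msg else TRUE
})

#' Empirical-Bayes batch-adjustment model
#'
#' Fitted location-scale batch model in the ComBat style: per-gene grand
#' intercept and preserved-design coefficients, pooled variance, and per-batch
#' per-gene location/scale effects shrunk by parametric empirical Bayes with
#' method-of-moments priors.
#'
#' @slot features feature ids the model was fitted on.
#' @slot batchLevels batch level names, in fitting order.
#' @slot alpha per-gene grand intercept (weighted by batch sizes).
#' @slot beta genes x preserved-columns coefficient matrix.
#' @slot sigma2 per-gene pooled variance after removing batch + design.
#' @slot gammaStar,delta2Star genes x batches shrunken location and scale.
#' @slot priors per-batch hyperparameters (gamma.bar, t2, a.prior, b.prior).
#' @slot preserveNames column names of the preserved design.
#'
#' @seealso [fitEbBatchModel()], [applyAdjustment()]
#' @export
setClass("BatchAdjustModel",
  representation(features = "character", batchLevels = "character",
                 alpha = "numeric", beta = "matrix", sigma2 = "numeric",
                 gammaStar = "matrix", delta2Star = "matrix",
                 priors = "list", preserveNames = "character"))

setValidity("BatchAdjustModel", function(object) {
  msg <- character()
  if (any(object@delta2Star <= 0))
    msg <- c(msg, "shrunken scale effects must be positive")
  if (!identical(colnames(object@gammaStar), object@batchLevels))
    msg <- c(msg, "gammaStar columns must match batch levels")
  if (length(msg)) msg else TRUE
})

#' Random-gene-set bias audit result
#'
#' Per-iteration AUCs of classifiers trained on randomly sampled gene sets,
#' together with the gene-set manifest so the identical sets can be replayed
#' on another variant of the same dataset for paired comparison.
#'
#' @slot aucs numeric vector of per-iteration AUCs, in `[0,1]`.
#' @slot manifest list of character vectors, the feature ids of each set.
#' @slot config list echoing the audit configuration.
#'
#' @seealso [runAudit()], [compareAudits()]
#' @export
setClass("AuditResult",
  representation(aucs = "numeric", manifest = "list", config = "list"))

setValidity("AuditResult", function(object) {
  msg <- character()
  if (any(object@aucs < 0 | object@aucs > 1))
    msg <- c(msg, "AUCs must lie in [0,1]")
  if (length(object@aucs) != length(object@manifest))
    msg <- c(msg, "one manifest entry per iteration required")
  if (length(msg)) msg else TRUE
})

#' Aggregated ensemble-mRMR feature ranking
#'
#' Mean rank scores over repeated subsampled mRMR runs. A feature at position
#' p of a length-L list scores L+1-p for that list and 0 when absent; the
#' final score is the mean over repeats and features are ordered by
#' descending score with lexical tie-break.
#'
#' @slot scores named numeric mean rank scores, in descending order.
#' @slot perRepeat list of the individual ranked lists (character vectors).
#' @slot listLength the L used for scoring.
#'
#' @seealso [ensembleRank()], [scanFeatureCounts()]
#' @export
setClass("FeatureRanking",
  representation(scores = "numeric", perRepeat = "list",
                 listLength = "numeric"))

setValidity("FeatureRanking", function(object) {
  msg <- character()
  if (any(object@scores < 0 | object@scores > object@listLength))
    msg <- c(msg, "scores must lie in [0, listLength]")
  if (is.unsorted(rev(object@scores)))
    msg <- c(msg, "scores must be in descending order")
  if (length(msg)) msg else TRUE
})
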