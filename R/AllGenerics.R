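#' @rdname exprMatrix
#' @export
setGeneric("exprMatrix", function(x, ...) standardGeneric("exprMatrix"))

#' @rdname sampleInfo
#' @export
setGeneric("sampleInfo", function(x, ...) standardGeneric("sampleInfo"))

#' @rdname trueFractions
#' @export
setGeneric("trueFractions", function(x) standardGeneric("trueFractions"))

#' @rdname trueDeGenes
#' @export
setGeneric("trueDeGenes", function(x) standardGeneric("trueDeGenes"))

#' @rdname latentSeverity
#' @export
setGeneric("latentSeverity", function(x) standardGeneric("latentSeverity"))

#' @rdname mriFeatures
#' @export
setGeneric("mriFeatures", function(x) standardGeneric("mriFeatures"))

#' @rdname cellFractions
#' @export
setGeneric("cellFractions", function(x) standardGeneric("cellFractions"))

#' @rdname absoluteScore
#' @export
setGeneric("absoluteScore", function(x) standardGeneric("absoluteScore"))

#' @rdname aucValues
#' @export
setGeneric("aucValues", function(x) standardGeneric("aucValues"))

#' @rdname setManifest
#' @export
setGeneric("setManifest", function(x) standardGeneric("setManifest"))

#' @rdname rankScores
#' @export
setGeneric("rankScores", function(x) standardGeneric("rankScores"))

#' @rdname signatureValues
#' @export
setGeneric("signatureValues", function(x) standardGeneric("signatureValues"))

#' @rdname signatureValues
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' Expression matrix accessor
#'
#' @param x a [SyntheticCohort-class].
#' @param ... unused.
#' @return genes x samples numeric matrix of log2 expression.
#' @export
#' @name exprMatrix
setMethod("exprMatrix", "SyntheticCohort", function(x, ...)
  SummarizedExperiment::assay(x@se, "log2"))

#' Sample metadata accessor
#'
#' @param x a [SyntheticCohort-class].
#' @param ... unused.
#' @return data.frame of per-sample metadata (diagnosis, sex, age, plate,
#'   site, subject_id, replicate_group), rows aligned with expression columns.
#' @export
#' @name sampleInfo
setMethod("sampleInfo", "SyntheticCohort", function(x, ...)
  as.data.frame(SummarizedExperiment::colData(x@se)))

#' Generating cell fractions of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return samples x cell types matrix.
#' @export
#' @name trueFractions
setMethod("trueFractions", "SyntheticCohort", function(x) x@trueFractions)

#' Planted disease genes of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return data.frame with columns gene, effect, sex.
#' @export
#' @name trueDeGenes
setMethod("trueDeGenes", "SyntheticCohort", function(x) x@trueDeGenes)

#' Latent severity variable of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return named numeric, one value per subject.
#' @export
#' @name latentSeverity
setMethod("latentSeverity", "SyntheticCohort", function(x) x@latentSeverity)

#' MRI-like feature block of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return subjects x features matrix.
#' @export
#' @name mriFeatures
setMethod("mriFeatures", "SyntheticCohort", function(x) x@mri)

#' Estimated cell fractions accessor
#' @param x a [CellFractionEstimates-class].
#' @return samples x cell types matrix of proportions.
#' @export
#' @name cellFractions
setMethod("cellFractions", "CellFractionEstimates", function(x) x@fractions)

#' Absolute immune signal accessor
#' @param x a [CellFractionEstimates-class].
#' @return named numeric of per-sample summed NNLS coefficients.
#' @export
#' @name absoluteScore
setMethod("absoluteScore", "CellFractionEstimates", function(x)
  x@absoluteScore)

#' Per-iteration audit AUCs
#' @param x an [AuditResult-class].
#' @return numeric vector of AUCs.
#' @export
#' @name aucValues
setMethod("aucValues", "AuditResult", function(x) x@aucs)

#' Gene-set manifest of an audit
#' @param x an [AuditResult-class].
#' @return list of character vectors, one per iteration.
#' @export
#' @name setManifest
setMethod("setManifest", "AuditResult", function(x) x@manifest)

#' Aggregated mRMR rank scores
#' @param x a [FeatureRanking-class].
#' @return named numeric of mean rank scores, descending.
#' @export
#' @name rankScores
setMethod("rankScores", "FeatureRanking", function(x) x@scores)

#' Signature matrix accessors
#' @param x a [SignatureMatrix-class].
#' @return `signatureValues()` the genes x cell types matrix; `markerMap()`
#'   the named list of marker gene ids per cell type.
#' @export
#' @name signatureValues
setMethod("signatureValues", "SignatureMatrix", function(x) x@values)

#' @rdname signatureValues
#' @export
setMethod("markerMap", "SignatureMatrix", function(x) x@markerMap)

#' @rdname cohortSignature
#' @export
setGeneric("cohortSignature", function(x) standardGeneric("cohortSignature"))

#' Signature matrix used to mix a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return the [SignatureMatrix-class] the expression was generated from.
#' @export
#' @name cohortSignature
setMethod("cohortSignature", "SyntheticCohort", function(x)
  S4Vectors::metadata(x@se)$signature)

setMethod("show", "SignatureMatrix", function(object) {
  v <- object@values
  cat("SignatureMatrix:", nrow(v), "genes x", ncol(v), "cell types\n")
  cat(" cell types:", paste(colnames(v), collapse = ", "), "\n")
  cat(" markers per type:",
      paste(vapply(object@markerMap, length, 1L), collapse = ", "), "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  md <- sampleInfo(object)
  cat("SyntheticCohort:", nrow(object@se), "features x", ncol(object@se),
      "samples\n")
  cat(" diagnosis:", paste(names(table(md$diagnosis)),
      table(md$diagnosis), collapse = ", "), "\n")
  cat(" plates:", length(unique(md$plate)), " sites:",
      length(unique(md$site)), " replicate samples:",
      sum(!is.na(md$replicate_group)) , "\n")
  cat(" planted genes:", nrow(object@trueDeGenes),
      " MRI features:", ncol(object@mri), "\n")
})

setMethod("show", "CellFractionEstimates", function(object) {
  cat("CellFractionEstimates:", nrow(object@fractions), "samples x",
      ncol(object@fractions), "cell types\n")
  cat(" mean fractions:",
      paste(sprintf("%s=%.3f", colnames(object@fractions),
                    colMeans(object@fractions)), collapse = ", "), "\n")
})

setMethod("show", "BatchAdjustModel", function(object) {
  cat("BatchAdjustModel:", length(object@features), "features,",
      length(object@batchLevels), "batches\n")
  cat(" preserved design:", paste(object@preserveNames, collapse = ", "),
      "\n")
})

setMethod("show", "AuditResult", function(object) {
  cat("AuditResult:", length(object@aucs), "iterations\n")
  cat(sprintf(" mean AUC %.3f +/- %.3f (sd)\n", mean(object@aucs),
              stats::sd(object@aucs)))
})

setMethod("show", "FeatureRanking", function(object) {
  cat("FeatureRanking:", length(object@scores), "features,",
      length(object@perRepeat), "repeats\n")
  top <- utils::head(names(object@scores), 5)
  cat(" top:", paste(top, collapse = ", "), "\n")
})
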