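#' Retain uniquely aligning probes
#'
#' Keeps exactly the probes whose genomic alignment is unique
#' (`n_genomic_matches == 1`).
#'
#' @param alignments data.frame with columns probe_id, n_genomic_matches,
#'   transcript_id, gene_symbol.
#' @return the filtered alignment data.frame.
#' @export
filterUniqueProbes <- function(alignments) {
  stopifnot(nrow(alignments) > 0,
            all(c("probe_id", "n_genomic_matches") %in% colnames(alignments)))
  alignments[alignments$n_genomic_matches == 1, , drop = FALSE]
}

#' Remove uninformative probes
#'
#' A probe is removed iff its mean linear signal falls below the
#' `signalQuantile` quantile of all probe means AND its coefficient of
#' variation (sd/mean across samples) falls below `cvThreshold` — the
#' conjunction, not the disjunction: a low-signal probe that still varies is
#' kept, as is a flat but bright one.
#'
#' @param intensities probes x samples linear-scale matrix with probe ids as
#'   rownames; at least two samples (the CV is undefined otherwise).
#' @param signalQuantile quantile of probe means defining "very low signal".
#' @param cvThreshold CV below which a probe counts as "low variation".
#' @return character vector of retained probe ids.
#' @export
filterUninformativeProbes <- function(intensities, signalQuantile = 0.1,
                                      cvThreshold = 0.05) {
  if (ncol(intensities) < 2)
    stop("coefficient of variation undefined for a single-sample matrix")
  m <- rowMeans(intensities)
  cv <- apply(intensities, 1, stats::sd) / m
  low_signal <- m < stats::quantile(m, signalQuantile)
  low_cv <- cv < cvThreshold
  rownames(intensities)[!(low_signal & low_cv)]
}

#' Build probe-set definitions
#'
#' Groups the surviving probes of each transcript into one probe-set,
#' dropping transcripts with fewer than `minProbes` survivors. Probe-sets are
#' keyed by transcript id.
#'
#' @param alignments probe alignment data.frame (see [filterUniqueProbes()]).
#' @param retainedProbes character vector of probe ids that passed filtering.
#' @param minProbes minimal probes per probe-set.
#' @return data.frame with columns probeset_id, probe_id, transcript_id,
#'   gene_symbol — a flat CDF-like map, one row per member probe.
#' @export
buildProbesets <- function(alignments, retainedProbes, minProbes = 3) {
  keep <- alignments[alignments$probe_id %in% retainedProbes, , drop = FALSE]
  counts <- table(keep$transcript_id)
  ok <- names(counts)[counts >= minProbes]
  keep <- keep[keep$transcript_id %in% ok, , drop = FALSE]
  keep <- keep[order(keep$transcript_id, keep$probe_id), , drop = FALSE]
  data.frame(probeset_id = keep$transcript_id, probe_id = keep$probe_id,
             transcript_id = keep$transcript_id,
             gene_symbol = keep$gene_symbol, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Summarise probe-sets to an expression matrix
#'
#' Probe-set value per sample is the median of the member probes' log2
#' intensities — robust and invariant to probe order.
#'
#' @param intensities probes x samples linear-scale matrix.
#' @param definition probe-set map from [buildProbesets()].
#' @return probe-sets x samples log2 expression matrix.
#' @export
summarizeProbesets <- function(intensities, definition) {
  missing <- setdiff(definition$probe_id, rownames(intensities))
  if (length(missing))
    stop("definition references probes absent from the intensity matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  lg <- log2(intensities)
  sets <- split(definition$probe_id, definition$probeset_id)
  out <- t(vapply(sets, function(p)
    apply(lg[p, , drop = FALSE], 2, stats::median),
    numeric(ncol(intensities))))
  colnames(out) <- colnames(intensities)
  out
}

#' Median-scale normalisation
#'
#' Shifts each sample column so its median equals the global median of the
#' column medians. A simple location normalisation standing in for heavier
#' rank-based schemes.
#'
#' @param matrix features x samples log2 matrix.
#' @return normalised matrix of the same shape.
#' @export
normalizeMedianScale <- function(matrix) {
  med <- apply(matrix, 2, stats::median)
  target <- stats::median(med)
  sweep(matrix, 2, med - target)
}

#' Filter features by standard deviation
#'
#' Retains the rows whose across-sample standard deviation is at least
#' `sdThreshold`, the expressed-feature filter applied after normalisation.
#'
#' @param matrix features x samples log2 matrix (two or more samples).
#' @param sdThreshold minimal row sd.
#' @return the filtered matrix.
#' @export
filterExpressedSd <- function(matrix, sdThreshold) {
  stopifnot(ncol(matrix) >= 2)
  sds <- apply(matrix, 1, stats::sd)
  matrix[sds >= sdThreshold, , drop = FALSE]
}
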