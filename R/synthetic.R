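#' Construct a synthetic cohort configuration
#'
#' Returns a [CohortConfig-class] with the standard confounded whole-blood
#' cohort as default: 346 subjects (half cases), a five-component Dirichlet
#' cell mixture whose neutrophil mean is shifted by +0.05 in cases, 18 plates
#' over 3 sites with plate assignment associated with diagnosis at 0.3, 100
#' planted disease genes at |log2 effect| 0.5 (30% active in one sex only),
#' technical noise (0.2) below biological noise (0.6), 10 technical-replicate
#' subjects, and a 136-feature MRI-like block coupled to latent severity.
#'
#' @param nSubjects,caseFraction,femaleFraction cohort design.
#' @param nGenes,nCellTypes,dirichletBase,neutrophilShift cell-mixture model;
#'   the first Dirichlet component is the neutrophil fraction.
#' @param nPlates,nSites,plateCaseAssoc,plateLocationSd,plateScaleSd batch
#'   structure and effect scales.
#' @param nDeGenes,deEffectLog2,sexSpecificFraction planted disease signal.
#' @param biologicalSd,technicalSd noise scales (log2 units).
#' @param nReplicateSubjects subjects profiled twice (technical replicates).
#' @param mriNFeatures,mriLoading,mriLatentShift MRI block parameters.
#' @param ageMeanCase,ageMeanControl,ageSd age model (years).
#' @param seed integer RNG seed.
#' @return a validated [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(nSubjects = 40, nGenes = 100, seed = 1)
#' @export
cohortConfig <- function(nSubjects = 346, caseFraction = 0.5,
                         femaleFraction = 0.55, nGenes = 2000,
                         nCellTypes = 5,
                         dirichletBase = c(neutrophil = 10, t_cell = 4,
                                           monocyte = 2.5, b_cell = 2,
                                           nk_cell = 1.5),
                         neutrophilShift = 0.05, nPlates = 18, nSites = 3,
                         plateCaseAssoc = 0.3, plateLocationSd = 0.3,
                         plateScaleSd = 0.1, nDeGenes = 100,
                         deEffectLog2 = 0.5, sexSpecificFraction = 0.3,
                         biologicalSd = 0.6, technicalSd = 0.2,
                         nReplicateSubjects = 10, mriNFeatures = 136,
                         mriLoading = 0.5, mriLatentShift = 1.5,
                         ageMeanCase = 79, ageMeanControl = 75, ageSd = 6,
                         seed = 1) {
  if (is.null(names(dirichletBase)))
    names(dirichletBase) <- paste0("cell", seq_along(dirichletBase))
  new("CohortConfig", nSubjects = nSubjects, caseFraction = caseFraction,
      femaleFraction = femaleFraction, nGenes = nGenes,
      nCellTypes = nCellTypes, dirichletBase = dirichletBase,
      neutrophilShift = neutrophilShift, nPlates = nPlates, nSites = nSites,
      plateCaseAssoc = plateCaseAssoc, plateLocationSd = plateLocationSd,
      plateScaleSd = plateScaleSd, nDeGenes = nDeGenes,
      deEffectLog2 = deEffectLog2, sexSpecificFraction = sexSpecificFraction,
      biologicalSd = biologicalSd, technicalSd = technicalSd,
      nReplicateSubjects = nReplicateSubjects, mriNFeatures = mriNFeatures,
      mriLoading = mriLoading, mriLatentShift = mriLatentShift,
      ageMeanCase = ageMeanCase, ageMeanControl = ageMeanControl,
      ageSd = ageSd, seed = seed)
}

#' Null variant of a cohort configuration
#'
#' Convenience wrapper setting every class-associated structure to zero:
#' no disease effect, no composition shift, no plate/site batch effects and
#' no plate-diagnosis association. Features then carry no information about
#' diagnosis, so any classification signal measured on such a cohort is bias
#' of the measuring procedure itself.
#'
#' @param ... passed to [cohortConfig()].
#' @return a [CohortConfig-class].
#' @export
nullCohortConfig <- function(...) {
  cohortConfig(neutrophilShift = 0, plateCaseAssoc = 0, plateLocationSd = 0,
               plateScaleSd = 0, nDeGenes = 0, deEffectLog2 = 0,
               mriLatentShift = 0, ageMeanCase = 75, ageMeanControl = 75,
               ...)
}

#' Generate a cell-type reference signature matrix
#'
#' Draws gamma-distributed linear-scale baseline expression and plants, for
#' each cell type, a disjoint block of marker genes whose value in that type
#' exceeds `markerFold` times the gene's mean over the other types.
#'
#' @param nGenes,nCellTypes matrix dimensions.
#' @param markersPerType marker genes planted per cell type (disjoint blocks).
#' @param markerFold minimal fold of a marker over its row mean in the other
#'   types.
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @return a [SignatureMatrix-class].
#' @examples
#' sig <- generateSignatureMatrix(200, 5, 20, 8, seed = 1)
#' @export
generateSignatureMatrix <- function(nGenes, nCellTypes, markersPerType,
                                    markerFold, seed = 1) {
  if (markersPerType * nCellTypes > nGenes)
    stop("marker demand (markersPerType * nCellTypes) exceeds nGenes")
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(nGenes))
  types <- paste0("cell", seq_len(nCellTypes))
  v <- matrix(stats::rgamma(nGenes * nCellTypes, shape = 2, scale = 50),
              nGenes, nCellTypes, dimnames = list(genes, types))
  markers <- vector("list", nCellTypes)
  names(markers) <- types
  for (c in seq_len(nCellTypes)) {
    idx <- ((c - 1) * markersPerType + 1):(c * markersPerType)
    boost <- markerFold * rowMeans(v[idx, -c, drop = FALSE]) *
      stats::runif(markersPerType, 1, 1.5)
    v[cbind(idx, c)] <- boost
    markers[[c]] <- genes[idx]
  }
  new("SignatureMatrix", values = v, markerMap = markers)
}

## Dirichlet draws via normalised gammas.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              n, length(alpha))
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

## Shift the mean of component 1 of a Dirichlet by delta while keeping the
## simplex: solve for the new concentration of component 1 given the others.
shift_neutrophil_alpha <- function(alpha, delta) {
  m <- alpha[1] / sum(alpha)
  m2 <- min(max(m + delta, 1e-6), 1 - 1e-6)
  a_rest <- sum(alpha[-1])
  alpha[1] <- a_rest * m2 / (1 - m2)
  alpha
}

rtruncnorm_5095 <- function(n, mean, sd) {
  lo <- stats::pnorm(50, mean, sd)
  hi <- stats::pnorm(95, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate a synthetic case-control cohort
#'
#' Builds a whole-blood-like cohort under a linear cell-mixture model: sample
#' expression is `log2(sum_c f_ic * S_gc * 2^effect + 1)` plus per-plate
#' location/scale effects, a site offset, per-subject biological noise and
#' per-measurement technical noise. Cell fractions are Dirichlet with the
#' neutrophil mean shifted in cases; planted disease genes carry a signed
#' log2 effect, a configurable fraction active in one sex only. Technical
#' replicates redraw only the technical noise. The MRI-like block is coupled
#' to a latent severity variable shifted in cases.
#'
#' @param config a [CohortConfig-class].
#' @param signature optional [SignatureMatrix-class]; generated from the
#'   config seed when missing (10 markers per type, fold 8).
#' @return a [SyntheticCohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(nSubjects = 30, nGenes = 120,
#'                                    nReplicateSubjects = 2, seed = 1))
#' @export
generateCohort <- function(config, signature = NULL) {
  validObject(config)
  n <- config@nSubjects
  nCase <- round(n * config@caseFraction)
  if (nCase < 1)
    stop("degenerate design: caseFraction * nSubjects < 1")
  if (is.null(signature)) {
    signature <- generateSignatureMatrix(
      config@nGenes, config@nCellTypes,
      markersPerType = max(3L, min(10L, config@nGenes %/%
                                     (2L * config@nCellTypes))),
      markerFold = 8, seed = config@seed + 7919)
    ## align cell-type names with the configured mixture components
    colnames(signature@values) <- names(config@dirichletBase)
    names(signature@markerMap) <- names(config@dirichletBase)
  }
  S <- signatureValues(signature)
  stopifnot(nrow(S) == config@nGenes)
  set.seed(config@seed)

  genes <- rownames(S)
  subjects <- sprintf("subj%04d", seq_len(n))
  diagnosis <- rep(c("AD", "CTL"), c(nCase, n - nCase))
  sex <- ifelse(stats::runif(n) < config@femaleFraction, "F", "M")
  age <- ifelse(diagnosis == "AD",
                rtruncnorm_5095(n, config@ageMeanCase, config@ageSd),
                rtruncnorm_5095(n, config@ageMeanControl, config@ageSd))

  ## plate assignment: with prob plateCaseAssoc draw from a diagnosis-specific
  ## half of the plates, otherwise uniformly; sites assigned independently
  plates <- seq_len(config@nPlates)
  firstHalf <- plates[seq_len(ceiling(config@nPlates / 2))]
  secondHalf <- setdiff(plates, firstHalf)
  if (length(secondHalf) == 0) secondHalf <- firstHalf
  plate <- integer(n)
  for (i in seq_len(n)) {
    pool <- if (stats::runif(1) < config@plateCaseAssoc) {
      if (diagnosis[i] == "AD") firstHalf else secondHalf
    } else plates
    plate[i] <- pool[sample.int(length(pool), 1)]
  }
  site <- sample.int(config@nSites, n, replace = TRUE)

  ## cell fractions: Dirichlet, neutrophil concentration shifted in cases
  alpha0 <- config@dirichletBase
  alpha1 <- shift_neutrophil_alpha(alpha0, config@neutrophilShift)
  fr <- matrix(0, n, config@nCellTypes,
               dimnames = list(subjects, names(alpha0)))
  isCase <- diagnosis == "AD"
  if (any(isCase)) fr[isCase, ] <- rdirichlet(sum(isCase), alpha1)
  if (any(!isCase)) fr[!isCase, ] <- rdirichlet(sum(!isCase), alpha0)

  ## planted disease genes with signed log2 effects, some sex-restricted
  nDe <- config@nDeGenes
  deGenes <- if (nDe > 0) sample(genes, nDe) else character()
  deSign <- if (nDe > 0) sample(c(-1, 1), nDe, replace = TRUE) else numeric()
  nSexSpec <- round(nDe * config@sexSpecificFraction)
  deSex <- rep("both", nDe)
  if (nSexSpec > 0)
    deSex[seq_len(nSexSpec)] <- sample(c("F", "M"), nSexSpec, replace = TRUE)
  deTab <- data.frame(gene = deGenes, effect = deSign * config@deEffectLog2,
                      sex = deSex, stringsAsFactors = FALSE)

  ## batch effect parameter draws (location per plate/site, log-scale per plate)
  plateLoc <- matrix(stats::rnorm(config@nGenes * config@nPlates, 0,
                                  config@plateLocationSd),
                     config@nGenes, config@nPlates)
  plateScale <- matrix(exp(stats::rnorm(config@nGenes * config@nPlates, 0,
                                        config@plateScaleSd)),
                       config@nGenes, config@nPlates)
  siteLoc <- matrix(stats::rnorm(config@nGenes * config@nSites, 0,
                                 config@plateLocationSd / 2),
                    config@nGenes, config@nSites)

  ## per-subject biology: mixture signal, planted effect, biological noise
  mix <- S %*% t(fr)                     # genes x subjects, linear scale
  if (nDe > 0) {
    deIdx <- match(deGenes, genes)
    for (k in seq_len(nDe)) {
      act <- isCase & (deSex[k] == "both" | sex == deSex[k])
      mix[deIdx[k], act] <- mix[deIdx[k], act] * 2^deTab$effect[k]
    }
  }
  bio <- matrix(stats::rnorm(config@nGenes * n, 0, config@biologicalSd),
                config@nGenes, n)
  base <- log2(mix + 1) + bio            # genes x subjects, log2 scale

  ## samples: one per subject plus technical replicates (same biology, same
  ## plate/site; fresh technical noise)
  nRep <- min(config@nReplicateSubjects, n)
  repSubjIdx <- if (nRep > 0) sort(sample.int(n, nRep)) else integer()
  subjOfSample <- c(seq_len(n), repSubjIdx)
  sampleIds <- c(subjects,
                 if (nRep > 0) paste0(subjects[repSubjIdx], "_rep"))
  nSamp <- length(subjOfSample)

  expr <- matrix(0, config@nGenes, nSamp,
                 dimnames = list(genes, sampleIds))
  for (s in seq_len(nSamp)) {
    j <- subjOfSample[s]
    tech <- stats::rnorm(config@nGenes, 0, config@technicalSd)
    expr[, s] <- base[, j] + plateLoc[, plate[j]] +
      plateScale[, plate[j]] * tech + siteLoc[, site[j]]
  }

  repGroup <- rep(NA_character_, nSamp)
  inRep <- subjOfSample %in% repSubjIdx
  repGroup[inRep] <- subjects[subjOfSample[inRep]]
  md <- S4Vectors::DataFrame(
    sample_id = sampleIds, subject_id = subjects[subjOfSample],
    diagnosis = diagnosis[subjOfSample], sex = sex[subjOfSample],
    age = age[subjOfSample], plate = factor(plate[subjOfSample]),
    site = factor(site[subjOfSample]), replicate_group = repGroup,
    row.names = sampleIds)

  ## latent severity and MRI block (per subject)
  latent <- stats::rnorm(n) + config@mriLatentShift * as.numeric(isCase)
  names(latent) <- subjects
  mri <- generateMriBlock(n, latent, config, seed = config@seed + 2027)
  rownames(mri) <- subjects

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = expr), colData = md,
    metadata = list(signature = signature))
  trueFr <- fr[subjOfSample, , drop = FALSE]
  rownames(trueFr) <- sampleIds
  new("SyntheticCohort", se = se, trueFractions = trueFr,
      trueDeGenes = deTab, latentSeverity = latent, mri = mri,
      config = config)
}

#' Generate an MRI-like feature block
#'
#' Each feature is `loading_j * t_i + noise` with unit Gaussian noise and
#' loadings drawn `N(0, mriLoading^2)`, so the block is informative about the
#' latent severity variable exactly to the extent the loadings are non-zero.
#'
#' @param nSubjects number of rows.
#' @param latentSeverity numeric of length `nSubjects` (finite).
#' @param config a [CohortConfig-class] (uses `mriNFeatures`, `mriLoading`).
#' @param seed integer RNG seed.
#' @return subjects x features numeric matrix.
#' @export
generateMriBlock <- function(nSubjects, latentSeverity, config,
                             seed = config@seed + 2027) {
  if (length(latentSeverity) != nSubjects)
    stop("latentSeverity length must equal nSubjects")
  if (any(!is.finite(latentSeverity)))
    stop("latentSeverity must be finite")
  set.seed(seed)
  p <- config@mriNFeatures
  load <- stats::rnorm(p, 0, config@mriLoading)
  noise <- matrix(stats::rnorm(nSubjects * p), nSubjects, p)
  m <- outer(latentSeverity, load) + noise
  colnames(m) <- sprintf("mri%03d", seq_len(p))
  m
}

#' Generate a probe-level fixture for the probe-set building chain
#'
#' Produces a probe alignment table and a linear-scale probe intensity matrix
#' with known counts of multimapping probes (`n_genomic_matches > 1`) and of
#' uninformative probes (low mean signal and low coefficient of variation),
#' plus the ground-truth retained probe set obtained by evaluating the two
#' filter predicates directly at generation time.
#'
#' @param nTranscripts,probesPerTranscript fixture dimensions.
#' @param multimapFraction,uninformativeFraction fractions in `[0,1)` of
#'   probes flagged multimapping / constructed low-signal-low-CV.
#' @param seed integer RNG seed.
#' @param nSamples intensity-matrix columns.
#' @param signalQuantile,cvThreshold thresholds used to evaluate the
#'   ground-truth uninformative predicate (the defaults of
#'   [filterUninformativeProbes()]).
#' @return list with `alignments` (data.frame: probe_id, n_genomic_matches,
#'   transcript_id, gene_symbol), `intensities` (probes x samples, linear
#'   scale) and `truth` (per-probe flags and the retained indicator).
#' @export
generateProbeFixture <- function(nTranscripts, probesPerTranscript,
                                 multimapFraction, uninformativeFraction,
                                 seed = 1, nSamples = 12,
                                 signalQuantile = 0.1, cvThreshold = 0.05) {
  if (multimapFraction < 0 || multimapFraction >= 1 ||
      uninformativeFraction < 0 || uninformativeFraction >= 1)
    stop("fractions must lie in [0,1)")
  set.seed(seed)
  nProbes <- nTranscripts * probesPerTranscript
  probes <- sprintf("probe%05d", seq_len(nProbes))
  tx <- sprintf("ENST%011d", rep(seq_len(nTranscripts),
                                 each = probesPerTranscript))
  gene <- sprintf("GENE%d", rep(seq_len(nTranscripts),
                                each = probesPerTranscript))
  nMulti <- floor(multimapFraction * nProbes)
  nUninf <- floor(uninformativeFraction * nProbes)
  multi <- sort(sample.int(nProbes, nMulti))
  uninf <- sort(sample(setdiff(seq_len(nProbes), multi), nUninf))
  matches <- rep(1L, nProbes)
  matches[multi] <- 1L + sample.int(5, nMulti, replace = TRUE)

  mu <- stats::runif(nProbes, 100, 1000)
  cv <- stats::runif(nProbes, 0.15, 0.4)
  mu[uninf] <- stats::runif(nUninf, 5, 15)
  cv[uninf] <- stats::runif(nUninf, 0.005, 0.03)
  intens <- matrix(0, nProbes, nSamples,
                   dimnames = list(probes, sprintf("s%02d", seq_len(nSamples))))
  for (i in seq_len(nProbes))
    intens[i, ] <- mu[i] * pmax(1 + stats::rnorm(nSamples, 0, cv[i]), 0.01)

  pm <- rowMeans(intens)
  pcv <- apply(intens, 1, stats::sd) / pm
  lowSignal <- pm < stats::quantile(pm, signalQuantile)
  lowCv <- pcv < cvThreshold
  truth <- data.frame(probe_id = probes,
                      is_multimapping = seq_len(nProbes) %in% multi,
                      is_uninformative = lowSignal & lowCv,
                      stringsAsFactors = FALSE)
  truth$retained <- !truth$is_multimapping & !truth$is_uninformative
  list(alignments = data.frame(probe_id = probes,
                               n_genomic_matches = matches,
                               transcript_id = tx, gene_symbol = gene,
                               stringsAsFactors = FALSE),
       intensities = intens, truth = truth)
}
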