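# BloodBiasAudit

Systematic-bias auditing and multimodal classification for case-control
whole-blood transcriptomics.

Whole-blood expression cohorts are a tempting substrate for disease
classifiers, but they are haunted by structure that has nothing to do with
disease biology: plate and site batch effects, shifts in white-blood-cell
composition between groups, and age/sex imbalance. Any of these lets a
classifier built from *randomly chosen* genes beat chance, which means
reported signature performance cannot be taken at face value.
`BloodBiasAudit` implements, end to end and fully testable without any
external download, the analysis chain needed to measure and remove that
inflation and then to build honestly evaluated classifiers:

- **Random-gene-set bias audit.** Draw gene sets of size *k* = 75 uniformly
  at random, train an L2-regularised logistic regression on each under
  leave-one-out cross-validation, and pool the out-of-fold scores into one
  rank-based (Mann-Whitney) AUC per set. Over many sets the mean AUC of an
  unbiased dataset is 0.5; any excess estimates dataset-level bias. Audits
  of different processing variants of the same data replay a shared gene-set
  manifest, so variants are compared by paired Wilcoxon signed-rank tests.
- **Cell-composition estimation.** Non-negative least squares of each
  sample's linear-scale expression onto a cell-type signature matrix
  (`min ||S w - m||`, `w >= 0`); fractions are `w / sum(w)` and the summed
  coefficients give an absolute immune signal. The z-scored neutrophil
  fraction is the composition covariate.
- **Stepwise batch adjustment.** Parametric empirical-Bayes location-scale
  correction (ComBat-style: method-of-moments priors, shrunken per-batch
  per-gene effects) applied sequentially for plate then site, followed by
  per-gene least-squares residualisation of the neutrophil covariate with
  the diagnosis term kept in the design.
- **Matched, ensemble-mRMR, multimodal classification.** Propensity-score
  matching on sex and age (greedy nearest-neighbour on the logit) to a
  class-balanced training set; two-step feature selection -- 50 mRMR runs
  (F-statistic relevance / mean |Pearson r| redundancy, quotient scheme) on
  stratified 80% subsamples, rank aggregation with the `L+1-p` / absent = 0
  rule, then a 50..500-feature scan with a "best AUC, at most 200 features,
  ties to the smaller count" rule; logistic / SVM / random-forest models
  tuned by nested stratified grid search; holdout and 50x5 repeated
  stratified CV evaluation with AUC, sensitivity, specificity and
  per-sex accuracy; concatenation fusion of transcriptomic and MRI feature
  blocks; permutation-sampled Shapley importance.
- **SAM-style differential expression** (moderated d statistic with fudge
  constant `s0` and permutation FDR), **rank-rank hypergeometric overlap**
  maps for comparing sex-stratified contrasts, and exact hypergeometric
  over-representation tests against the expressed-gene background.
- **A synthetic-cohort generator** that emulates the statistical structure
  all of the above assumes -- Dirichlet cell mixtures with a group-shifted
  neutrophil fraction, 18-plate/3-site batch structure optionally associated
  with diagnosis, sex-restricted log2 disease effects, technical replicates
  with technical < biological noise, and a 136-feature MRI-like block
  coupled to a latent severity variable -- so every stage is exercised
  against known ground truth.

## Worked example

Generate a confounded cohort, audit it, adjust, and audit again with the
same gene sets:

```r
library(BloodBiasAudit)

cfg <- cohortConfig(nSubjects = 160, nGenes = 1000, nDeGenes = 50,
                    nPlates = 8, nReplicateSubjects = 8, seed = 7)
coh <- generateCohort(cfg)

md   <- sampleInfo(coh)
keep <- !grepl("_rep$", rownames(md))        # one sample per subject
X    <- exprMatrix(coh)[, keep]; mdk <- md[keep, ]

man <- sampleGeneSets(rownames(X), setSize = 75, nIterations = 50, seed = 11)
raw <- runAudit(X, mdk$diagnosis, manifest = man)
raw
#> AuditResult: 50 iterations
#>  mean AUC 0.744 +/- 0.078 (sd)

adj  <- adjustStepwise(X, mdk, steps = c("plate", "site"), preserve = NULL)
fr   <- estimateFractions(adj, cohortSignature(coh))
fr
#> CellFractionEstimates: 160 samples x 5 cell types
#>  mean fractions: neutrophil=0.525, t_cell=0.204, monocyte=0.114, b_cell=0.083, nk_cell=0.073
neut <- scaleCovariate(fr, "neutrophil")
adj2 <- residualizeContinuous(adj, neut, mdk$diagnosis)

after <- runAudit(adj2, mdk$diagnosis, manifest = man)
after
#> AuditResult: 50 iterations
#>  mean AUC 0.581 +/- 0.070 (sd)
cmp <- compareAudits(raw, after)
#> paired Wilcoxon p = 7.79e-10, mean AUC drop = 0.163
```

The raw cohort lets random gene sets classify at AUC 0.744 -- that excess
over 0.5 is bias from the planted plate-diagnosis association and the
neutrophil shift, on top of the genuine disease effect. After label-blind
plate/site adjustment and neutrophil residualisation the same gene sets
drop to 0.581: the technical and compositional share of the signal is gone,
the planted disease effect remains. Technical replicates bound platform
noise:

```r
replicateConcordance(exprMatrix(coh), md)
#> within-replicate r = 0.962, between-sample r = 0.467
```

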