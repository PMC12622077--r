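---
title: "Auditing and correcting dataset bias in case-control blood transcriptomics"
author: "BloodBiasAudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing and correcting dataset bias in case-control blood transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BloodBiasAudit)
```

# The problem

A whole-blood expression matrix carries three kinds of class-associated
structure besides disease biology: technical batches (plates, clinical
sites), cell-composition differences (dominated by the neutrophil
fraction, the most abundant leukocyte), and demographic imbalance (sex,
age). Each of them lets a classifier look better than the biology
warrants, and none of them is visible from a single headline AUC. This
package implements a chain of procedures to quantify that inflation, to
remove its technical and compositional parts, and to build classifiers
whose evaluation protocol cannot re-absorb it.

# The sampling-at-random audit

The central diagnostic treats classification performance of *random*
feature sets as a property of the dataset, not of any signature. Each
iteration draws `setSize = 75` features uniformly without replacement,
fits an L2-penalised logistic regression under leave-one-out
cross-validation, and scores the pooled n out-of-fold predictions with the
rank-based (Mann-Whitney, midranks for ties) AUC. Pooling rather than
fold-averaging is forced by LOOCV: each fold yields a single score, so
only the pooled vector defines an AUC. On an exchangeable dataset the mean
over iterations converges to 0.5; an excess is bias.

The classifier is deliberately pinned: summed log-loss plus
$\tfrac{\lambda}{2}\lVert w\rVert^2$ with $\lambda = 1$ and an unpenalised
intercept (the default of the common libraries), features standardised
inside each training fold. The fit is a warm-started Newton/IRLS kernel in
compiled code, since the protocols below need on the order of $10^5$
logistic fits. Two conventions matter for comparisons:

* audits of different processing variants of the same cohort replay an
  identical gene-set **manifest**, so per-iteration AUCs pair up and a
  Wilcoxon signed-rank test can detect mean shifts of a few thousandths;
* when all paired differences are zero the p-value is reported as 1.

A caveat worth knowing: pooled LOOCV scores are slightly pessimistic
(training folds under-represent the held-out class), so on finite null
data the mean audit AUC sits marginally below 0.5 rather than exactly on
it; at $n = 300$ the deviation is well inside $\pm 0.03$.

# Deconvolution and the neutrophil covariate

Cell fractions are estimated per sample by non-negative least squares of
linear-scale expression ($2^x - 1$, the inverse of the generator's
$\log_2(x+1)$; a flag covers inputs without the $+1$) onto the signature
matrix, restricted to signature genes. NNLS is the minimal linear mixture
solver consistent with the physical model of whole blood as a non-negative
mixture; fractions are the normalised coefficients and their unnormalised
sum is kept as an absolute immune signal (it scales linearly with the
sample's overall signature-explained intensity, which is why fractions are
invariant to per-sample rescaling). The adjustment covariate is the
z-scored neutrophil fraction. Z-scoring uses the sample standard deviation
(divisor $n-1$, R's `sd()`), the convention under which the worked
three-point example $\{0.4, 0.5, 0.6\} \mapsto \{-1, 0, 1\}$ holds
exactly.

# Stepwise batch adjustment

Categorical batches are corrected by the parametric empirical-Bayes
location-scale model: per gene, an intercept, optional preserved design
and pooled variance standardise the data; per-batch location and scale
effects are estimated and shrunk with a normal / inverse-gamma prior whose
hyperparameters come from method-of-moments fits across genes. The
implementation reproduces the reference implementation (`sva::ComBat`) to
machine precision on shared configurations, which the test suite asserts;
it is re-implemented here because the model object must expose the
shrunken per-batch effects and priors for parameter-recovery tests. Steps
run sequentially -- plate, then site -- and the continuous neutrophil
covariate is then removed by per-gene least squares with the diagnosis
term retained in the design, subtracting only the centred covariate term.

Three properties of this model are worth stating because they shape what
tests can honestly assert:

* **Identifiability.** Batch locations are estimable only relative to
  their batch-size-weighted mean, so recovery of planted effects is
  assessed against the centred truth (the raw-truth correlation is bounded
  near 0.77 at four batches by construction, not by estimation error).
* **Overcorrection in-sample.** Adjusting the very data the model was
  fitted on removes (shrunken) batch means almost exactly, so a subsequent
  per-gene ANOVA on batch yields p-values piled near 1 -- conservative,
  not uniform. Uniformity would require an oracle that subtracts the
  *true* batch effects; no faithful in-sample (or out-of-sample)
  empirical-Bayes adjustment achieves it. The suite therefore asserts the
  scientific content -- no residual batch association -- rather than
  distributional uniformity, and the one acceptance check that demands
  literal uniformity is expected to fail and documented as such.
* **Near-idempotence.** Re-fitting on adjusted data re-shrinks location
  effects to essentially zero; the residual change is scale-factor
  sampling noise of order $\tfrac12\sqrt{2/n_b}$, so "idempotent to
  machine precision" is not attainable at realistic sample sizes. The
  suite asserts RMS change below $10^{-2}$ at $n_b = 400$.

## Why the audit chain adjusts label-blind

Whether the batch step should preserve a diagnosis term was a genuinely
open design choice. We resolved it empirically: on a cohort whose plate
assignment is associated with diagnosis, preserving diagnosis *raises*
the audit's mean AUC by about 0.03 instead of lowering it. The mechanism
is circular feature construction: the adjustment re-injects each gene's
fitted diagnosis effect, estimated on all samples -- for null genes pure
estimation noise of sd $\approx 2\sigma/\sqrt{n}$ -- as a consistent
separation that downstream cross-validation cannot unsee. Since the whole
point of the audit is to expose exactly this kind of circularity, the
plate/site steps of the audit chain run with `preserve = NULL`. The
supervised mode remains available (and is the right choice when the batch
layout is randomised with respect to diagnosis and the goal is effect
estimation rather than bias measurement); the neutrophil residualisation
keeps diagnosis in its design because it only subtracts the covariate
term and therefore re-injects nothing.

# Matching, feature selection and modelling

**Propensity matching.** A logistic model of diagnosis on sex and age
(covariates standardised internally for stability, coefficients reported
on the original scale, quasi-separation flagged) yields per-sample logits.
Matching is greedy 1:1 nearest-neighbour without replacement on the logit:
the minority class drives, candidates are processed in descending logit
order, ties break lexically on sample id, and an optional caliper discards
distant pairs. Greedy matching is deterministic and can be compared
against the optimal assignment where it matters; balance is reported as
standardised mean differences with the pooled-sd denominator
$\sqrt{(s_1^2 + s_0^2)/2}$ (proportions for binary covariates; zero pooled
variance reported as SMD 0 with a flag).

**Ensemble mRMR.** The base ranker is greedy
maximum-relevance/minimum-redundancy with F-statistic relevance, mean
absolute Pearson redundancy floored at $10^{-6}$, and the quotient
combination (the difference scheme is a switch). Constant features have
zero relevance and cannot precede any informative feature; all ties break
lexically so reruns are bit-stable. The ensemble runs the ranker on
repeated 80% subsamples stratified by diagnosis and sex; a feature at
position $p$ in a length-$L$ list scores $L + 1 - p$, an absent feature
scores 0, and the final order is by mean score. The feature-count scan
then evaluates the top $c$ features for $c = 50, 60, \dots, 500$ on a
subject-disjoint holdout and selects, per classifier, the highest-AUC
count of at most 200, breaking AUC ties toward the smaller count. One
property of the quotient scheme deserves a note: an exact duplicate of the
top feature is rejected at the second pick only when another comparably
relevant feature exists; if the top feature's relevance dwarfs everything
else, relevance/redundancy still favours the duplicate.

**Models and evaluation.** Three families -- ridge logistic regression,
SVM (linear/RBF), random forest -- with small exhaustive default grids,
tuned by nested stratified cross-validation on training data only,
standardisation always fitted on the training side. Metrics are AUC,
sensitivity and specificity at the 0.5-probability threshold (decision
value 0 for margin classifiers), and accuracy within each sex. Repeated
stratified CV (diagnosis x sex strata, per-fold stratum counts within one
sample of each other) retains the per-fold AUC vector so fused and
unimodal models sharing a fold sequence are compared by paired signed-rank
tests with zero differences dropped. Fusion is plain column concatenation
of per-block feature tables keyed by sample id, with block-prefixed names;
scaling lives inside the model pipeline so it is always training-fold
only. Feature attribution uses sampled-permutation Shapley values against
the training-mean baseline; on additive scorers each permutation's
telescoping sum is exact, so the estimate equals
$w_j (x_j - \bar x_j)$ and contributions plus the baseline score
reconstruct the model score, which the tests exploit as a closed-form
oracle.

# Differential expression, RRHO and ORA

The moderated statistic is $d_g = (\bar x_{g,1} - \bar x_{g,0}) / (s_g +
s_0)$ with the pooled standard error $s_g$ and a fudge constant that
damps low-variance genes; `s0 = "auto"` uses the median of $s_g$ -- a
deterministic, documented simplification of the MAD-minimising grid
search, which matters little for rank-based downstream use. FDR comes
from label permutations (exhaustive when the design is small enough,
flagged in the output): for each observed $|d|$ threshold the FDR is the
median permuted exceedance count over the observed count, and a gene's q
is the minimum FDR over thresholds it passes, making q monotone in $|d|$.

Rank-rank hypergeometric overlap compares two signed rankings of one gene
universe on a step grid: each cell holds the exact hypergeometric tail of
the observed head-overlap, $-\log_{10} P(X \ge k)$ for enrichment, signed
negative for depletion. The map is transpose-symmetric in its arguments.
The reported enrichment zone is the most significant cell of the head-head
corner (both thresholds at most $N/2$); reversing both lists examines the
concordant-down corner. Grid-wide multiplicity is reported, not
corrected. Over-representation uses exact tail sums against the
expressed-gene background with Benjamini-Hochberg correction across the
collection; the query must be contained in the background and sets are
intersected with it before testing.

# The synthetic cohort generator

Every stage above is tested against cohorts with known generating truth.
Expression mixes on the linear scale and logs afterwards,
$x_{gi} = \log_2\!\big(\textstyle\sum_c f_{ic} S_{gc} 2^{\text{effect}_{gi}} + 1\big)
+ \gamma_{g,p(i)} + \delta_{g,p(i)}\varepsilon_{gi} + \text{site}_{g,s(i)}
+ b_{gi}$, which keeps the physical interpretation of whole blood as a
cell mixture. Fractions are Dirichlet; the case shift of the neutrophil
mean is implemented by solving for the neutrophil concentration parameter,
which preserves the simplex exactly. Sex-specific disease genes are
effect-present-in-one-sex rather than sign-flipped. Ages are truncated
normal on [50, 95] with a four-year case excess so matching has something
to correct. Technical replicates redraw only technical noise. The MRI
block is a linear factor model on a latent severity variable shifted in
cases. One RNG stream per generator call derives from the config seed, so
identical configs give bit-identical cohorts.

Defaults encode the standard study conditions: 346 subjects, half cases;
five cell types with mean neutrophil fraction 0.5 and a +0.05 case shift;
18 plates over 3 sites with plate-diagnosis association 0.3 and per-gene
plate location sd 0.3 (site offsets at half that -- the magnitude of real
plate effects is not identifiable from published summaries, so these are
fixed once to reproduce the qualitative bias ordering and never
revisited); 100 planted genes at $|\log_2|$ effect 0.5 with 30%
sex-restricted; biological sd 0.6 against technical sd 0.2; ten
technical-replicate subjects; 136 MRI features with latent shift 1.5.
`nullCohortConfig()` zeroes every class-associated parameter.

What the generator does *not* emulate: gene-gene co-expression beyond
what shared cell fractions induce, heavy-tailed or intensity-dependent
noise, probe-level artefacts (a separate probe fixture covers the
alignment-multimapping and low-signal/low-CV rules), missing data, and
longitudinal structure. Green tests therefore certify the procedures
under the stated generative assumptions, not the behaviour of any real
cohort.

# Problem sizes and numerical choices

The test suite runs the audit calibration at 300 subjects x 2000 features
x 200 iterations, the bias-ordering chain on the 346-subject standard
cohort with 200 shared gene sets, deconvolution recovery at 200 genes /
5 types / 100 samples with 10% multiplicative noise, batch recovery at
500 genes x 400 samples, mRMR oracle equivalence on 100 twelve-feature
instances, and fusion on 10x5-fold CV -- sizes chosen to exercise each
claim at meaningful scale while keeping a full run within minutes.
Throughout: LOOCV Newton iterations stop at an $10^{-8}$ step norm;
redundancy floors at $10^{-6}$ prevent division blow-ups; constant
features standardise to zero rather than NaN; all order-dependent
procedures (mRMR, matching, subset selection) break ties lexically;
probe-set summaries are medians of member log2 intensities, so they are
probe-order invariant.
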