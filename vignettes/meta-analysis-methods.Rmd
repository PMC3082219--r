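---
title: "Cross-platform meta-analysis for single-gene tumor markers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform meta-analysis for single-gene tumor markers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamarker)
```

## The problem

Individual microarray studies of papillary thyroid carcinoma (PTC) versus
benign thyroid nodules are small — a dozen to a few dozen samples — while the
feature space has thousands to tens of thousands of probes. Feature selection
under those conditions is unstable: a classifier trained on one study rarely
transfers to another, not because the biology differs but because each
laboratory, platform and platform generation imprints its own systematic bias
on the measurements. **metamarker** implements a meta-analysis pipeline that
merges several such studies into one cohort large enough for robust marker
selection, and a validation arm that checks a selected marker on an
independent RT-qPCR cohort.

The pipeline stages are fixed in this order:

1. probe collapse and cross-study feature matching (RefSeq-set keys),
2. column-wise merging and collective quantile normalization,
3. sequential batch-bias removal by Distance Weighted Discrimination (DWD),
4. nearest-shrunken-centroid (NSC) classification with leave-one-out
   cross-validation and cross-study train/test matrices,
5. moderated-t differential expression with BH correction,
6. a competitive accumulated-t gene-set test,
7. (independent arm) geNorm reference selection, relative quantification,
   ROC thresholding and confusion metrics on qPCR Ct data.

The ordering collapse → intersect → merge → quantile → DWD is a design
decision: quantile normalization equalises the marginal distribution of every
array before DWD estimates directional location bias, so the DWD direction is
not spent on distributional differences that quantile normalization removes
anyway.

## Feature matching by RefSeq-set equality

Two probes are considered the same feature only when their *complete* sets of
annotated RefSeq transcript identifiers are equal. Overlap- or
gene-ID-based matching can merge probes that interrogate different splice
variants, which measure genuinely different quantities. The canonical key is
the sorted, de-duplicated, `|`-joined identifier set, so keys are independent
of annotation order. Multiple probes carrying one key are collapsed by the
per-sample **median** (midpoint of the central pair for even counts), which
is robust to a single aberrant probe. Probes with no annotation are dropped
and counted, not rescued into a sentinel bucket: an unannotated probe has no
defensible cross-platform identity.

## Quantile normalization

All samples of the merged cohort are normalised collectively: each column is
mapped onto the vector of row-wise means of the column-sorted matrix, ranks
preserved, ties receiving the mean of the reference values at the tied ranks
(the conventional tie rule). The operation is idempotent and equalises the
empirical distribution of every array exactly; it deliberately does *not*
address gene-wise location bias between studies — that is DWD's job.

## Distance Weighted Discrimination

DWD solves

$$\min_{w,\beta,\xi}\; \sum_i \frac{1}{r_i} + C\sum_i \xi_i
\quad\text{s.t.}\quad r_i = y_i(w\cdot x_i+\beta)+\xi_i,\; r_i>0,\;
\xi_i\ge 0,\; \lVert w\rVert\le 1,$$

with $y_i=\pm1$ the *dataset* (not tumor-class) labels. Unlike an SVM, every
sample contributes to the direction through its reciprocal margin, which is
what makes the direction a good estimate of the overall dataset shift in
high dimensions. Integration then subtracts each dataset's mean projection
along $w$: $x_i' = x_i - m_{b(i)} w$. Components orthogonal to $w$ are
untouched, and after adjustment each dataset's mean projects exactly to zero.

Numerical choices:

* The slack variables are eliminated analytically. For margin $m$ the inner
  minimisation gives the smooth convex loss $V(m)=1/m$ if
  $m\ge 1/\sqrt{C}$ and $V(m)=2\sqrt{C}-Cm$ otherwise; the problem becomes
  $\min_{\lVert w\rVert\le 1,\beta}\sum_i V(y_i(w\cdot x_i+\beta))$.
* Because $V$ is strictly decreasing, the norm constraint is always active,
  so we optimise over the unit sphere via the normalised parameterisation
  $w=u/\lVert u\rVert$ with BFGS, after an SVD reduction to the sample span
  (any component of $w$ orthogonal to the span wastes norm without changing
  a margin). Initialisation is deterministic: the mean-difference direction
  and the midpoint offset. The solver is validated against an exhaustive
  angle/offset grid search on two-feature problems.
* Default penalty $C = 100/\mathrm{median}^2(\text{pairwise distances})$, a
  standard scale-free heuristic; the problem's scaling identity
  ($x\to cx$, $C\to C/c^2$ leaves $w$ unchanged) is verified in the tests.
* More than two studies are merged **sequentially** (DWD is a two-class
  construction), by default largest study first; the merge order is
  configurable through a `plan`. Each step's removed mean gap is recorded in
  a provenance table.
* A fitted model refuses to adjust any sample set other than the one it was
  fitted on: adding a sample changes every batch mean, so reuse would be
  silently wrong.

## Nearest shrunken centroids

For gene $i$ and class $k$ the standardized contrast is
$d_{ik} = (\bar x_{ik}-\bar x_i)/(m_k (s_i+s_0))$ with
$m_k=\sqrt{1/n_k-1/n}$ (the standard error factor of a class centroid
against the overall centroid), $s_i$ the pooled within-class SD and
$s_0=\mathrm{median}_i(s_i)$ guarding against near-zero variances. Soft
thresholding $d'_{ik}=\mathrm{sign}(d_{ik})(|d_{ik}|-\Delta)_+$ at a grid of
30 equispaced thresholds from 0 to $\max|d_{ik}|$ yields a classifier family
with embedded gene selection. Prediction minimises
$\sum_i (x^*_i-\bar x'_{ik})^2/(s_i+s_0)^2 - 2\log\pi_k$; exact score ties go
to the larger prior, then lexicographically.

Leave-one-out cross-validation refits everything (centroids, $s_i$, $s_0$)
per fold; the threshold grid is computed once on the full data so that
per-threshold error counts aggregate coherently across folds. The chosen
threshold attains minimal CV error, and among minimisers the **largest**
threshold — the fewest-genes rule — wins. This is what drives the pipeline
toward single-gene signatures when one dominant marker exists.

Two consumers build on this: the cross-study matrix (train on one study at
its own internally cross-validated threshold, test on every other; diagonal
= within-study loocv), run on pre- and post-integration data to quantify how
much dataset bias blocks transfer; and the iterative marker-removal loop,
which repeatedly removes the chosen signature and re-runs, exposing whether
discrimination rests on one gene or on a redundant reservoir. The removal
loop stops at a configurable accuracy floor (default 0.9) or when the matrix
is exhausted.

## Moderated differential expression

The two-class comparison uses empirical-Bayes moderated variances: a scaled
inverse-chi-squared prior $(d_0, s_0^2)$ estimated by moment matching on
$\log s_g^2$ (trigamma inversion, delegated to `limma::fitFDist`), posterior
variance $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0+d)$, and a t-statistic
with $d_0+d$ degrees of freedom. Setting $d_0=0$ recovers the ordinary
pooled t exactly; $d_0=\infty$ gives a common-variance z-like statistic —
both limits are tested. P-values are BH-adjusted (`stats::p.adjust`). A
non-specific variance filter (default: lowest 20% of overall variances,
configurable, off in all oracle tests) is applied before testing and its
count logged.

Each gene also receives a single-feature sensitivity and specificity: the
gene is used as a univariate classifier whose direction comes from the sign
of its log fold-change and whose cut-point maximises Youden's J over all
midpoints (ties toward higher sensitivity). The threshold rule is this
package's choice — reasonable alternatives exist, and published per-gene
sens/spec tables computed under other conventions (notably for
down-regulated genes) need not agree.

## Competitive gene-set test

Gene-level t-statistics are accumulated over a set as the **mean** t (mean
|t| for the "mixed" direction) — mean rather than sum so the statistic is
comparable across set sizes. The null is competitive: `B` random gene sets
of the same size drawn without replacement from the tested universe, with
$p=(1+\#\{\text{null}\ge\text{obs}\})/(B+1)$ (mirrored for "down"). `B`
defaults to 10,000 and a seed is mandatory. The per-study variant reruns the
whole t + set-test chain inside each study and summarises cross-study sign
concordance of the significant sets. Both one-sided modes and the two-sided
"mixed" mode are exposed, since set direction conventions differ between
analyses.

## qPCR validation arm

* **Reference-gene stability (geNorm):** for assays $j,k$ the pairwise
  variation $V_{jk}$ is the SD over samples of $\log_2(q_j/q_k)$; the
  stability $M_j$ is the mean of $V_{jk}$ over partners. $M$ is invariant to
  per-sample loading factors, which is the point: a good reference tracks
  loading and nothing else. The single-pass ranking is the default (the
  pipeline only needs the winner); classical stepwise exclusion is available.
* **Relative quantification:** replicates are averaged on the Ct scale (the
  common convention), then normalised expression is
  $2^{-(Ct_\text{target}-Ct_\text{ref})}$, PCR efficiency fixed at 2
  (configurable).
* **Decision threshold:** full ROC over all midpoints between consecutive
  sorted unique values. The default policy, `max-sens`, keeps sensitivity at
  1 and maximises specificity — the clinically motivated choice when a
  missed carcinoma is costlier than a false alarm; `youden` is available.
  Ties resolve to the lower threshold; constant scores give a degenerate
  single-point ROC and an `NA` threshold.
* **Confusion metrics:** counts plus sens/spec/PPV/NPV/accuracy, with
  zero-denominator ratios reported as `NA` (never 0) and no internal
  rounding. The seven-entity truth is binarised PTC vs everything else.

## The synthetic data generator

The generator is first-class, tested code that defines the study conditions
under which the pipeline is exercised:

* **Cohort shape:** 4 studies with (9, 8, 23, 7) carcinoma and
  (9, 8, 28, 7) benign samples — 47 vs 52 in total; an 82-sample qPCR cohort
  over 7 histological entities with 19 carcinomas.
* **Signal:** one dominant marker at log2 fold-change 3.3, one 20-gene
  up-regulated "ECM-like" set at +1.5, six 15-gene down-regulated
  "metabolic-like" sets at −1. (Published fold-change reports for such a
  marker can disagree between text and tables — e.g. 8-fold versus
  log2FC 3.3 ≈ 10-fold; the generator fixes 3.3 and does not arbitrate.)
* **Bias model:** an additive per-gene per-study shift
  $\sim N(0, \text{batch\_sd}^2)$, i.e. a pure location bias — exactly the
  structure that mean subtraction along a direction can remove. A
  multiplicative per-study scale would additionally be handled by quantile
  normalization; hybridisation-level artefacts are *not* modelled. Default
  `batch_sd = 1.0` against `noise_sd = 0.5`: strong enough that a 1-NN
  classifier predicts study membership almost perfectly before integration,
  which is the regime in which DWD's effect is measurable.
* **Probe universe:** a 2,000-gene universe, 85% covered per study, 10% of
  covered genes carried by duplicate probes (identical annotation sets, so
  the median rule is exercised), 10% of genes with two RefSeq-like
  identifiers (so set-keys are exercised). Planted marker and pathway genes
  are always covered in every study — otherwise a coverage draw could delete
  the planted structure from the shared feature space and the run would test
  nothing.
* **qPCR plate:** per-sample loading factors shared by all assays, reference
  assays with graded stability SDs (0.05, 0.3, 0.6; the first is the planted
  geNorm winner), a 36-fold target elevation in PTC, and triplicate Ct noise.

What passing tests on this generator do **not** show: robustness to
non-additive batch effects, missing values, annotation errors, probe
saturation, or entity-specific normalisation artefacts (the kind that
produce false positives in medullary/anaplastic carcinomas in real qPCR
data — the generator plants none, so simulated validation metrics are
cleaner than real ones). Those caveats are inherent to any location-shift
simulation, and the package surfaces per-entity distributions so real-data
anomalies remain visible rather than corrected away.

## Problem sizes and determinism

All simulation-backed checks run at the cohort shape above, with gene
universes between 150 and 2,000 genes depending on how many seeds the check
repeats over; the package's own test suite uses 10–20 seeds for the
simulation-based claims. Every random stage (generator, permutation nulls)
takes an explicit integer seed, and an end-to-end rerun with the same
configuration reproduces the persisted report byte for byte; this is tested.

## A worked run

```{r example, eval = FALSE}
cfg <- meta_config(sim = sim_config(seed = 1))
report <- run_meta(cfg, out_dir = "run1")
report$loocv_accuracy     # leave-one-out accuracy of the chosen classifier
report$signature          # the selected gene signature (feature keys)
report$cross_study        # train/test accuracies before and after DWD

qrep <- run_qpcr(qpcr_run_config(qpcr_config(seed = 2)))
qrep$metrics              # sens/spec/PPV/NPV/accuracy of the qPCR decision
```

## Known limitations

* DWD is fitted by a smooth reformulation plus BFGS on the sphere, not an
  interior-point SOCP; on the tested problem sizes it matches the exhaustive
  oracle to well under 0.1%, but it inherits BFGS's dependence on a sane
  initialisation (the deterministic mean-difference start has been
  sufficient everywhere it is tested).
* The moderated-t stage covers exactly the two-group design; no covariates,
  array weights or duplicate-correlation structure.
* The set test performs gene sampling, which ignores inter-gene correlation;
  its p-values are calibrated against random gene sets, not against
  sample-label permutations.
* The qPCR arm assumes a single fixed amplification efficiency per run.
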