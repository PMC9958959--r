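---
title: "Fusing multiview functional brain networks by joint embedding"
author: "fbnfuse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing multiview functional brain networks by joint embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbnfuse)
```

## The problem

A functional brain network (FBN) is a weighted graph whose nodes are brain
regions of interest (ROIs) and whose edges quantify statistical dependence
between the regions' resting-state BOLD time courses. Different estimators
see different aspects of that dependence: Pearson correlation (PC) measures
full marginal correlation, sparse representation (SR) captures
partial-correlation structure under an l1 sparsity prior, mutual
information (MI) is sensitive to nonlinear coupling, and correlation's
correlation (CC) describes high-order similarity of whole connectivity
profiles. Any single view is an incomplete picture; `fbnfuse` fuses the
four views into one network per subject through a *joint embedding* of the
ROIs, and evaluates the fused networks in a patient-versus-control
classification protocol.

## The model

For one subject, let $A^{(k)} \in \mathbb{R}^{n\times n}$,
$k = 1,\dots,m$, be the $m$ single-view connectivity matrices, stacked
into a third-order tensor. The joint embedding solves

$$
\min_{P, R^{(k)}}\; \tfrac12 \sum_{k=1}^m
  \big\lVert A^{(k)} - P R^{(k)} P^\top \big\rVert_F^2
  + \tfrac{\alpha}{2} \sum_{k=1}^m \lVert R^{(k)} \rVert_F^2,
\qquad P^\top P = I,
$$

where row $p_i$ of $P \in \mathbb{R}^{n\times r}$ is ROI $i$'s latent
representation shared by all views, $R^{(k)} \in \mathbb{R}^{r\times r}$
carries the view-specific interactions, and $\alpha$ guards against
overfitting. The fused network connects ROIs whose latent profiles
co-vary: $W_{ij} = \mathrm{corr}(p_i, p_j)$ (the default `pearson`
reconstruction; the Gram alternative $W = PP^\top$ is available as
`inner`).

The model has an eigenvector-centrality reading: for a single symmetric
slice and $r = 1$ the stationary point of the factorization is the
dominant eigenvector of $A$ — the eigenvector-centrality score vector —
and for $r > 1$ the column space of $P$ is the top-$r$ eigenspace. The
package verifies this equivalence against a dense eigendecomposition in
its test suite (`eigenvectorCentrality()`, `rescalALS()` with
`reorthonormalize` on).

### Fitting

`rescalALS()` alternates the two closed-form updates of the
regularized alternating-least-squares scheme:

* embedding update
  $P \gets \big[\sum_k (A^{(k)} P R^{(k)\top} + A^{(k)\top} P
  R^{(k)})\big]\big[\sum_k (R^{(k)} R^{(k)\top} + R^{(k)\top} R^{(k)}) +
  \alpha I\big]^{-1}$;
* core update $R^{(k)} = V\,(S \circ (U^\top A^{(k)} U))\,V^\top$ with
  $P = U\Sigma V^\top$ and $S_{ij} = \sigma_i\sigma_j /
  (\sigma_i^2\sigma_j^2 + \alpha)$, the exact ridge minimizer for fixed
  $P$.

$P$ is initialized with the $r$ leading eigenvectors of
$\sum_k (A^{(k)} + A^{(k)\top})$ and the cores with seeded standard-normal
draws. After every sweep the normalized residual
$\mathrm{fit} = \sum_k \lVert A^{(k)} - P R^{(k)} P^\top \rVert_F^2 /
\lVert \chi \rVert_F^2$ (with $\chi = \sum_k A^{(k)}$) is recorded;
iteration stops when the between-sweep change falls below `epsilon`
(default `1e-5`; the attainable fit floor depends on the noise level, so
an absolute fit target would not terminate reliably) or after `tMax`
(default 100) sweeps.

Two numerical points deserve emphasis:

* **The embedding update is exact only on the constraint set.** Its
  denominator presumes $P^\top P = I$. Without re-orthonormalization the
  iteration is the literal alternating scheme and can oscillate on noisy
  tensors; `rescalALS()` therefore tracks the best-fit sweep and returns
  it (with a warning) whenever the final residual exceeds the initial one,
  so a returned embedding never ends worse than it started. Setting
  `reorthonormalize = TRUE` projects $P$ back onto the constraint set by a
  thin QR after each update, which restores monotone descent in practice
  and realizes the centrality equivalence exactly; the flag is off by
  default to match the plain update scheme.
* **Regularization is scale-coupled.** $\alpha$ competes with the slice
  energy $\lVert A^{(k)} \rVert_F^2$. The default $\alpha = 10$ is the
  value at which classification performance peaked for raw 116-ROI
  networks, whose slice energy is of order $10^3$. `stackTensor()`
  rescales slices to unit Frobenius norm by default (so that the
  differently scaled MI view cannot dominate the least-squares objective),
  and on that scale the matched value is $\alpha \approx 10^{-2}$ — the
  `pipelineConfig()` default. Passing $\alpha = 10$ to unit-norm slices
  makes the ridge term crush the factors toward zero.

## Synthetic study conditions

Real rs-fMRI inputs (preprocessed BOLD time series per ROI) are expensive
and external, so the package ships a generator pair that reproduces the
statistical structure the method relies on, at desk scale:

* `simulateBoldCohort()` draws a two-class cohort of multivariate normal
  ROI series with AR(1) temporal autocorrelation. Both classes share a
  modular (block) correlation base — blocks of 10 ROIs at within-block
  correlation 0.35, between-block 0.05 — and the patient class has a
  planted correlation shift on a fixed edge set. Defaults: 20 subjects
  per class, 30 ROIs, 150 timepoints, 20 planted edges shifted by +0.4,
  AR(1) coefficient 0.3 (a realistic value for a 2-s TR after band-pass
  filtering). Class matrices are projected to the nearest
  positive-definite correlation matrix by eigenvalue clipping at 1e-6,
  re-symmetrization and unit-diagonal rescaling, and the projected
  matrices are returned as the ground truth.
* `simulateTensor()` draws exactly low-rank symmetric-slice tensors
  $A^{(k)} = P_0 R_0^{(k)} P_0^\top + \text{noise}$ with a shared random
  orthonormal factor, the generative form assumed by the factorization.
  Noiseless slices keep their diagonals by default so that they are
  exactly rank $r_0$ and subspace recovery can be tested to machine
  precision; `zeroDiagonal = TRUE` applies the pipeline's zero-diagonal
  convention instead (those slices are full-rank, so the exact-recovery
  regime no longer applies).

What the generator does *not* emulate: hemodynamic response shapes,
scanner noise spectra, head-motion artifacts, site effects, or
heterogeneous ROI sizes. Passing tests on this cohort therefore
demonstrate the correctness and internal consistency of the estimators,
the factorization, and the protocol — not clinical performance on real
rs-fMRI.

For the 30-ROI cohort the fusion rank is set to 12: the sensitivity
analysis on the 116-ROI parcellation located the optimum at
$r \in [40, 50]$, i.e. roughly $0.4\,n$, and 12 preserves that ratio.

## The classification protocol

`loocvEvaluate()` implements a nested leave-one-out protocol with strict
train/test separation:

1. **Outer loop** over subjects; subject $o$ is held out.
2. **Inner loop** on the remaining subjects selects, independently per
   estimator, the sparsity parameter (removal proportion for PC/MI/CC
   over `0, 0.1, ..., 0.9, 0.99`; SR penalty over $2^{-5},\dots,2^5$):
   each inner cycle holds out one training subject, scores every
   candidate by the accuracy of a t-test + linear-SVM classifier on that
   subject, and records the best candidate (ties to the earlier grid
   position); the candidate recorded most often wins. Because the inner
   cycle of fold $o$ holding out $i$ trains on the same subjects as the
   inner cycle of fold $i$ holding out $o$, the implementation evaluates
   each unordered pair once (a leave-two-out table), halving the work
   without changing a single decision.
3. Per-subject **fused networks** are built at the selected parameters
   (estimate, threshold, stack, factor, reconstruct). Fusion never sees
   the labels, so fused matrices are cached across folds.
4. **Feature selection**: upper-triangle edge weights
   ($n(n-1)/2$ features; 6670 at $n = 116$) are screened by a two-sided
   pooled-variance two-sample t-test at `pThreshold` (canonical values
   0.01, 0.05, 0.001, 0.005; default 0.001), fitted on training subjects
   only. Zero-variance features are never selected; a fold whose
   selection is empty falls back to the training-majority prediction and
   logs the event rather than aborting the protocol.
5. A **linear SVM** (cost fixed at 1) predicts the held-out subject;
   decision values feed the AUC.

Reported metrics: ACC, SEN, SPE, BAC = (SEN+SPE)/2, PPV, NPV, and the
rank-statistic (Mann–Whitney) AUC with midrank tie handling, with the
patient class (ASD) positive throughout. Undefined ratios are reported
as NaN and flagged, never silently zeroed. The fusion parameters
$(\alpha, r)$ are fixed configuration constants, not tuned in the inner
loop — only the initial-FBN parameters are — matching the protocol that
tunes view sparsity per fold and examines $(\alpha, r)$ sensitivity
separately.

As a separability diagnostic independent of any classifier,
`interclassDistance()` computes the Euclidean distance between the two
class-mean upper-triangle vectors. The package compares joint-embedding
fusion against the naive `averagingFusion()` baseline with this
diagnostic (`fusionDistanceDiagnostic()`), computed at the modal view
parameters selected by the protocol across folds — the same networks the
classifier consumes.

## Design choices in ambiguous territory

Choices the method description leaves open, and what this package does:

* **Standardization.** All estimators operate on per-ROI centered,
  unit-l2-norm columns. PC and equal-width-bin MI are invariant to this;
  for SR it makes the $\lambda$ grid meaningful across datasets.
* **SR solver.** The l1 regressions are solved by warm-started cyclic
  coordinate descent on the Gram system (tolerance 1e-6 on the largest
  coefficient change, default budget 10000 sweeps, warm starts down a
  geometric $\lambda$ path). Solutions agree with an independent
  coordinate-descent implementation (glmnet) to ~1e-8. The asymmetric
  coefficient matrix is symmetrized as $(W + W^\top)/2$.
* **MI estimator.** Plug-in histogram MI in nats with
  $\lceil\sqrt{v}\rceil$ equal-width bins per signal over its observed
  range and the $0\log 0 = 0$ convention. Kernel estimators were left
  out deliberately: at $v \approx 150$ the histogram estimator is the
  standard, assumption-light choice.
* **CC self-entries.** The low-order profile of an ROI keeps its
  self-correlation of 1, so column $i$ of $W$ is the full profile; the
  high-order diagonal is zeroed afterwards.
* **Thresholding.** `proportionalThreshold()` ranks edges by absolute
  weight — strong negative edges survive — and removes exactly
  $\lfloor p\,E\rfloor$ of the weakest, with magnitude ties resolved by
  retaining the smaller row-major pair index. Degenerate inputs (all-tied
  magnitudes) therefore threshold deterministically.
* **Reconstruction mode.** `pearson` is the default (correlating embedded
  ROI profiles); the Gram-matrix variant `W = PP^T` is available as
  `inner` since both appear in the method's description and which one
  produced the reported numbers is not resolvable from it.
* **Inner-loop accuracy.** With one held-out subject per inner cycle,
  per-cycle accuracy is binary; grid-order tie-breaking makes the
  selection deterministic. Whether parameters were re-selected per outer
  fold or fixed once globally is ambiguous in the source description;
  this package re-selects per outer fold, the leakage-safe reading.
* **t-test variant.** Pooled-variance two-sample by default (the
  conventional choice of the era's toolchains); Welch is available behind
  the `welch` flag of `ttestSelect()`.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
factorization recovery on $30 \times 30 \times 4$ tensors of rank 5;
the full nested protocol on the default cohort (40 subjects, 30 ROIs,
150 timepoints, 435 edge features, full parameter grids — 44 candidate
parameters per fold). These sizes were chosen so that every stage, from
estimator to nested cross-validation, is exercised end-to-end in minutes
on a single core while keeping the statistical regime (features ≫
subjects, weak planted effects) faithful to the application.

## Behavior under label permutation

Leave-one-out cross-validation has a well-known anti-learning artifact on
null data: with balanced classes the held-out subject's class always has
one fewer training member, so any classifier that drifts toward the
training majority — including the zero-feature majority fallback and an
SVM fitted on noise features — predicts the *opposite* class more often
than not. On the default synthetic cohort with permuted labels the
protocol's accuracy collapses far below 50% rather than hovering at
chance: most folds select no features at the strict threshold and fall
back to the (always wrong) training majority. This is a property of
balanced LOOCV itself, not of the fusion, and is the reason fold
outcomes must not be modelled as independent Bernoulli draws when
building chance bands for this protocol. Leakage would show as
permutation accuracy *above* chance; the package's leakage tests check
the selection decisions directly instead.

## Known limitations

* The literal alternating scheme does not enforce the orthogonality
  constraint; without `reorthonormalize` its fit trace is guaranteed
  non-increasing only on noiseless low-rank fixtures.
* Histogram MI is biased upward at short series length; comparisons
  across $v$ should use a fixed bin count.
* The linear-SVM protocol with t-test screening is faithful to the
  evaluation being reproduced, not a recommendation; modern pipelines
  would cross-validate the screening threshold and report permutation
  p-values.
* No rs-fMRI preprocessing is included: inputs are assumed to be cleaned,
  parcellated ROI time series.
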