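---
title: "Affinity regression: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affinity regression: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
bilinear model and how it is estimated, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and
the design choices made where the design was genuinely open.

## The model and its assumptions

Matched tumor profiles give a gene expression matrix `Y` (genes x samples,
log scale, mean-centered per gene) and a protein abundance matrix `P`
(samples x proteins, mean-centered per protein). A binary motif-hit matrix
`D` (genes x TFs) encodes which transcription factors plausibly regulate
each gene, derived from promoter binding-site predictions and consumed here
as pre-computed GMT gene sets. Affinity regression assumes expression
variation across samples is explained by a bilinear interaction between the
two feature spaces:

    D W P' ≈ Y,

with `W` (TFs x proteins) the interaction matrix to be learned. The model is
linear in both feature spaces: combinatorial TF logic, enhancer regulation,
and sample-specific nonlinearities are outside its scope. Protein levels are
treated as noisy readouts of pathway activity; the model's usefulness rests
on pooling over all target genes of each TF.

## Estimation through the reduced similarity system

Fitting `D W P' = Y` directly couples `N x M` equations. Left-multiplying by
`Y'` produces

    (Y'D) W P' = Y'Y,

a system whose output is the sample-similarity matrix: this is the form the
package solves. With `A = Y'D` and `B` the SVD-reduced protein
representation (`P = U Σ V'`, `B = U_r Σ_r`), vectorization gives a ridge
problem

    min || (B ⊗ A) vec(W_r) - vec(Y'Y) ||² + λ ||vec(W_r)||²,

whose solution is computed through the SVDs of `A` and `B` alone:
writing `A = U_a Σ_a V_a'`, the solution is
`W_r = V_a [ (Σ_a U_a' (Y'Y) U_r Σ_r) / (σ_a² σ_b² + λ) ]` with the division
elementwise, and `W = W_r V_r'` maps back to the original protein basis. The
Kronecker product is never materialized, so fitting costs little more than
two small SVDs. The test suite checks this factored path against an
explicit Kronecker-ridge oracle on random instances (relative Frobenius
error below 1e-8).

Two consequences of the reduction matter in practice:

* **Affine indeterminacy.** The reduction constrains `D W P'` only through
  `Y'`-projections, so held-out predictions `ŷ = D W p` are meaningful up to
  an affine transform. All evaluation therefore uses Spearman rank
  correlation, which is invariant to that indeterminacy.
* **Identifiability.** Components of `W` along protein directions in which
  `P` does not vary (or that the SVD truncation removes) are not
  identifiable. Noise-free recovery of a planted `W` is exact only when
  `rank(Y'D) = Q` and the truncation retains the full protein rank — the
  test suite constructs such instances explicitly.

## Parameters, defaults, and why

* `variance_fraction` (default **0.99**): fraction of squared-singular-value
  mass of `P` retained before fitting. The truncation exists to drop
  numerically negligible directions and to stabilize the system when the
  protein panel is large; the retained mass directly bounds how much of `W`
  remains identifiable (roughly, the correlation with a planted `W` cannot
  exceed the square root of the retained fraction of `W`'s mass). At RPPA
  scale (tens to ~200 antibodies, fewer than the training samples)
  aggressive truncation buys little and biases `W`, so the default retains
  99% of the variance. Set it lower only when proteins far outnumber
  samples.
* `lambda` (ridge penalty): selected by k-fold cross-validation over a
  13-point log-spaced grid on `[1e-3, 1e3]` (`select_lambda()`), maximizing
  mean held-out Spearman correlation, ties broken toward the smaller
  penalty. The factorization is shared across the grid, so selection costs
  one SVD per fold.
* `sd_threshold` (default **0.65**, log2 units): genes with expression
  standard deviation strictly below the threshold are removed before
  centering; a gene exactly at the threshold is kept.
* `jaccard_threshold` (default **0.8**): TFs whose target sets are
  near-duplicates are pruned greedily in lexicographic id order, dropping a
  TF whose Jaccard similarity with any retained TF reaches the threshold.
  The original pruning list of the motif collection is not public, so the
  criterion is exposed as a parameter.
* Association testing: `n_perm = 1000` randomized interaction matrices,
  FDR 10%; drug signatures: alpha grid of 20 points on `[0.001, 0.2]`,
  100 stability iterations on 80% subsamples, minimum selection count 10;
  survival: univariate Wald p < 0.001, 100 stepwise repeats on 80%
  subsamples with a 50% selection-frequency consensus, 40%/40% risk tails.

## Permutation nulls for subtype associations

Activity-subtype associations use the Mann-Whitney U statistic. Its null
distribution is estimated by randomizing the *trained model* rather than
the labels: each permutation reassigns the rows (TF identities) of `W`,
recomputes activities through the model, and recomputes every entity's
statistic. This preserves the weight distribution and the correlation
structure induced by `P` while breaking entity-specific structure, and makes
the test deliberately conservative: an entity is called only when its group
contrast exceeds what arbitrary rows of the same trained model produce.
Entrywise shuffling of `W` is available as `null = "entrywise"`. Empirical
p-values use the add-one estimator `(1 + #exceedances) / (1 + n_perm)`, so
they are never zero; Benjamini-Hochberg correction is applied across
entities within each comparison, and assignments must additionally match the
sign of the group contrast within the assigned subtype.

## Drug signatures and cross-drug transfer

Per drug, the elastic-net mixing parameter is chosen by cross-validation on
the full data over the restricted alpha range (which controls signature
size); each stability iteration refits on a random 80% of cell lines with
the penalty chosen per fit at the one-standard-error rule (`lambda.1se`).
The one-SE rule is what keeps null drugs honest: with no signal the most
regularized model within one SE of the CV minimum is the intercept-only
model, so noise responses yield empty signatures, while an informative
feature survives essentially every subsample. A feature enters the signature
when it is selected in at least `min_count` iterations with a consistent
coefficient sign. Cross-drug transfer trains a ridge model per drug and
evaluates it out-of-fold, so every prediction comes from a model that never
saw that cell line.

## Survival analysis

Deaths attributed to other causes are removed before modeling. The
univariate screen fits one Cox model per protein activity; the multivariate
step repeats bidirectional stepwise AIC selection from the empty model on
random 80% subsamples — repeated subsampling is what stabilizes selection
among the highly correlated inferred activities — and the final model refits
the covariates selected in at least half the repeats. Validation-cohort
patients are ranked by linear predictor; the top and bottom 40% (floors on
each tail) form the high- and low-risk groups compared by log-rank test.
Ties in the Cox partial likelihood use the Efron approximation; the test
suite checks coefficients against a brute-force partial-likelihood maximizer
on small untied instances.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws `D ~ Bernoulli(motif_density)`, protein profiles
as per-subtype mean shifts (scale `effect_sd`) plus unit Gaussian noise
(column-centered), a low-rank Gaussian `W_true`, and
`Y = D W_true P' + ε` with `sd(ε) = noise_sd · sd(signal)`, plus gene-level
baselines so `Y` arrives uncentered. `W_true` carries one global scale
chosen so the per-gene signal sds straddle the 0.65 filter (per-gene
rescaling would break the exact bilinear identity, so variability comes from
motif-count heterogeneity plus this single scale). Optional planted
TF-specific subtype shifts support power studies; activity-driven drug
responses and exponential survival times with independent censoring complete
the study designs. Everything is reproducible bit-for-bit from one seed
(R's default Mersenne-Twister generator).

Deliberately not emulated: array probe effects, batch structure, heavy
tails, and — importantly — mRNA–protein decoupling. In the generator,
protein levels are the root cause of all expression variation and gene
rows are nearly noise-free linear readouts of it, so analyses built on raw
gene features are *stronger* on synthetic data than they are on real data.
Passing tests therefore demonstrate correctness of the machinery (recovery,
calibration, stratification), not the real-data advantage of inferred
protein activity over per-gene mRNA features, which rests on biology the
generator does not model.

## Numerical choices

* **Deterministic SVD signs**: every left singular vector is flipped so its
  largest-magnitude entry is positive; fits are bit-reproducible.
* **Fold hygiene**: cross-validation recenters genes and proteins with
  training-fold means, selects the penalty inside the fold, and centers
  held-out samples with the training means — the only leakage-free choice.
  A dedicated test perturbs a held-out sample and asserts the fold model is
  unchanged.
* **Rank tolerance**: singular values below `max(dim) · eps · σ_max` are
  dropped, so `lambda = 0` is usable on full-rank designs.
* **Tie-breaks**: lambda ties go to the smaller penalty; nearest-neighbor
  ties to the earlier training sample; risk-ranking ties to stable sample
  order (logged); motif-redundancy ties keep the lexicographically first TF.
* **Missing data**: gene rows (expression) and protein columns (RPPA) with
  any missing value are dropped at load time, avoiding imputation
  assumptions; missing GI50 entries are masked pairwise.

## Problem sizes used by the tests and the acceptance script

Unit tests run on cohorts of roughly 150–300 genes and 24–64 samples. The
end-to-end checks use the generator's default cohort (500 genes, 64 samples,
40 TFs, 20 proteins, noise at 10% of the signal sd, four balanced subtypes)
— large enough for stable recovery while a full fit takes well under a
second — with 200-permutation nulls for association calibration; the
survival study uses a 714-sample cohort split 460/254 into discovery and
validation, mirroring the discovery/validation proportions of large breast
cancer survival cohorts. These sizes are stated here as the package's
simulation design.

## Known limitations

* Linear-fixed motif representation: no TF combinatorics, no enhancers.
* `Y'DW` mixes proteins through `W'D'DW`; inferred activities are
  informative linear combinations rather than unbiased per-protein
  estimates, so single-protein conclusions need the association and
  survival machinery (nulls, validation cohorts), not raw activity values.
* The permutation null for associations is conservative by construction
  (see above); at small TF panels, ranking by empirical q is more
  informative than the absolute q values.
* PAM50-style subtype calling, motif scanning, and raw-array normalization
  are upstream of this package and consumed as inputs.
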