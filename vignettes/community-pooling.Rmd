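---
title: "Hierarchical community pooling for brain-network regression"
author: "connectopool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical community pooling for brain-network regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`connectopool` performs graph-level regression on weighted brain networks:
each subject contributes a graph $G = (A, X)$ with a symmetric nonnegative
adjacency $A \in \mathbb{R}^{N \times N}$ (structural connectivity) and node
features $X \in \mathbb{R}^{N \times d}$ (rows of the functional network, an
all-ones column, or PCA-reduced features), together with a continuous score
$y$. The model maps $G \mapsto \hat y$ through repeated rounds of

1. **Graph convolution.** $Z = \sigma(\tilde D^{-1/2} \tilde A \tilde D^{-1/2}
   Z_{\text{in}} \theta)$ with $\tilde A = A + I$, $\tilde D$ the row-sum
   degree matrix of $\tilde A$, and $\sigma$ a ReLU; two stacked layers per
   block by default, so each node aggregates a two-hop neighborhood. The
   unit self-loop guarantees positive degrees, and the normalized operator
   has spectrum in $[-1, 1]$.
2. **Community pooling** (the core operator). Nodes are scored by how
   densely other nodes surround them in latent space: with the pairwise
   distance matrix $S_{ij} = \lVert Z_i - Z_j \rVert_{L_1}$, the center
   probability is $P = \mathrm{softmax}(1 - \mathrm{normalize}[\textstyle\sum_j
   S_{ij}])$, where `normalize` is min–max scaling of the row-sum vector to
   $[0,1]$ (an all-zero vector when every row sum is equal, making $P$
   uniform). The $M = \lceil rN \rceil$ highest-probability nodes become
   community centers ($r$ is the pooling ratio, 0.5 by default); every other
   node joins its nearest center; and each community is summarized as
   $\hat Z_i = Z_{c_i} + \sum_{v_j \in \Omega_i} Z_{v_j} / (S_{c_i,v_j} +
   \varepsilon)$. The coarse adjacency is the block sum of $A$ over community
   pairs, with purely diagonal (same-node) mass dropped so that off-diagonal
   edge mass is conserved.
3. **Readout.** Each scale contributes $Z_G = \sigma(W \hat Z)$ with a
   per-scale trainable $W \in \mathbb{R}^{1 \times M}$. Readouts from all
   scales are fused (concatenation by default; sum and average are
   available) and a small MLP (hidden sizes 64 and 32) produces $\hat y$.

Training minimizes $L = \eta_1\,\ell_{\mathrm{MSE}}(\hat y, y) +
\eta_2\,\ell_{\mathrm{community}}$, where the community term is the summed
per-member MSE between each non-center member's latent feature and its
center's, across all scales; $\eta_1 = 0.5$ and $\eta_2 = 0.01$ by default.
For a batch, both terms are averaged over the batch's graphs (the batch
reduction is a package choice). Optimization uses Adam (batch size 256,
clamped to the training-set size), initial learning rate $10^{-3}$ decayed
per epoch by $(1 - \text{epoch}/\text{max})^{0.9}$, $L_2$ weight decay
$10^{-5}$, early stopping when the validation loss has not improved by at
least $10^{-6}$ for 20 consecutive epochs (500 epochs maximum), returning
the best-validation parameters. Evaluation is 5-fold cross-validated MAE
with an inner 10% validation split carved from each training fold.

## Design choices at genuinely open points

* **L1 versus L2 distance.** The pooling operator's defining formula uses
  the L1 norm while the surrounding description speaks of Euclidean
  distance. The package implements both (`distance = "l1"` or `"l2"`),
  defaults to the formula's L1, and leaves the discrepancy documented
  rather than resolved.
* **Gradients and the hard selection.** Top-M center selection is a hard,
  non-differentiable operation. During backpropagation the selection, the
  membership assignment, and the $1/(S+\varepsilon)$ aggregation
  coefficients are treated as constants of the forward pass; gradients flow
  through every latent-feature term and through the community-coherence
  loss, which is the mechanism that shapes the latent geometry. Finite
  difference checks therefore target the MLP and readout parameters (exact
  in all regimes) and all parameters in regimes where pooling is the
  identity.
* **Numerical guards.** $\varepsilon = 10^{-6}$ in the aggregation
  denominator keeps coincident latent features finite; min–max degeneracy
  falls back to a uniform center probability; all ties (probability and
  distance) break toward the smaller node index, making the entire forward
  pass deterministic.
* **Readout initialization.** Pooled features are entrywise nonnegative
  (post-ReLU features, positive aggregation weights), so a sign-symmetric
  random readout weight frequently yields an all-negative preactivation —
  a dead ReLU readout with no regression gradient. Readout weights are
  therefore initialized positive, jittered around mean pooling
  ($U(0.5, 1.5)/M$); graph-convolution and MLP weights use Glorot-uniform
  initialization, biases start at zero, all under the config seed.
* **Per-scale readout weights** (rather than shared): $M$ differs across
  scales, so each scale owns its $1 \times M$ readout.
* **Adjacency renormalization.** Each scale's coarsened adjacency is
  re-normalized fresh before its convolution block.
* **PCA scope.** `reduceFeatures()` fits the projection on the sample
  subset the caller passes (the training portion, to avoid leakage) and
  projects everyone.

## Interpretability pipeline

The final pooling module's centers are a subject's **effecting nodes**,
mapped to the original atlas through the center-lineage: a coarse node's
atlas identity is the atlas root of its chain of centers, so the effecting
set always has the final scale's size (31 nodes for a 246-node atlas with
three modules at ratio 0.5). Per group, `nodeFrequency()` counts the
fraction of subjects selecting each atlas node. `nmiScore()` quantifies the
similarity of two groups' frequency profiles: both vectors are discretized
into 10 equal-width bins over $[0,1]$ and the discrete mutual information
of the node-wise joint bin assignment is normalized by the arithmetic mean
of the marginal entropies. The exact NMI operationalization (binning and
normalization) is not fixed by the method's description; this choice is the
package's and is cross-checked against an independent implementation in the
tests. `permutationTest()` assesses significance one-sided: low NMI means
dissimilar profiles, subjects are reshuffled into pseudo-groups of the
original sizes (100 permutations by default), and the add-one estimator
$p = (1 + \#\{\mathrm{null} \le \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$
guarantees validity at finite permutation counts. The pooled subject sets
are ordered canonically before permuting, so the p-value is invariant to
which group is labeled first.

## What the synthetic generator emulates

Real cohorts of this kind (hundreds of subjects, a few hundred atlas
regions, restricted-access imaging) cannot ship with a package, so
`synthConfig()`/`makeCohort()` generate cohorts that preserve the features
of the data that the method's machinery relies on:

* **Community structure:** a planted-partition topology (within-community
  edge probability 0.6, between 0.1) with exponential edge weights of mean
  0.1 — small relative to the unit self-loop, as tract-count-style weights
  are after typical scaling, so message passing mixes neighborhoods without
  drowning each node's own signal.
* **Feature organization:** each community has a fixed standard-normal
  prototype, drawn once per cohort from the seed — the broad functional
  organization of the brain is shared across subjects — and nodes scatter
  around their prototype with per-coordinate noise 0.3.
* **Salient signal nodes:** a planted subset (default 5 of 30, spread
  across communities) models behaviorally relevant connector-hub regions:
  they connect to all communities (edge probability 0.8 to every node) and
  their features sit at the prototype centroid plus a per-subject
  activation $s_k \sim N(0,1)$ along a fixed direction (magnitude 0.5 per
  coordinate by default). Both properties place them centrally — in
  the latent space the density-based center score favors exactly such
  between-cluster hubs.
* **Targets:** $y = \sum_k c_k \cdot \overline{X_{\mathrm{sig}_k}} +
  N(0, 0.1)$, a linear readout of the signal nodes' mean features — so
  ground truth exists for both regression quality and effecting-node
  enrichment. Two-group cohorts give group B its own disjoint signal set
  (targets and hub structure), planting a group difference for the
  permutation pipeline; `protoSeed` lets replicate cohorts share one
  population feature geometry, which is what replicated significance
  studies assume.

What the generator does **not** emulate: heavy-tailed degree
distributions, spatially correlated noise, score distributions of real
behavioral instruments, or any atlas geometry. Passing tests on these
cohorts demonstrates that the implementation recovers structure the model
class can represent under the stated training recipe — not that the method
attains any particular accuracy on real imaging cohorts.

## Problem sizes used in the shipped studies

The reference regression study uses 200 subjects on a 30-node atlas with 4
communities and 5 signal nodes, two pooling modules at ratio 0.5, hidden
dimension 64, and the full training recipe — small enough to run a 5-fold
cross-validation in well under a minute on one core (the training core is
C++), large enough that the mean-predictor baseline is beaten by a wide
margin. The group-difference study trains one model on a two-group cohort
(disjoint signal sets, 200 subjects) and evaluates the permutation test on
replicate cohorts of 400 subjects (200 per group, 50 permutations each)
drawn from the same population. The learning-rate schedule, early stopping,
and determinism contracts are checked exactly.

## Known limitations

* Gradients do not flow through center selection or the aggregation
  coefficients; architectures that depend on differentiable pooling are out
  of scope by design.
* The readout ReLU can zero negative information before fusion; this
  follows the method as written.
* Signed (negative) edge weights are rejected rather than modeled;
  `clipNegative`/`symmetrize` flags handle marginally noncompliant inputs
  explicitly.
* With exactly tied latent features, permutation invariance of predictions
  holds only up to the deterministic index tie-break.
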