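---
title: "Multi-atlas structure-aware graph-transformer classification of functional connectomes"
author: "atlasfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas structure-aware graph-transformer classification of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atlasfuse)
```

This vignette is the package's own account of its model, its assumptions,
the tunable parameters that matter, the synthetic-data generator that makes
the pipeline testable without imaging data, and the numerical and design
choices taken where the architecture was genuinely open.

## From time series to graphs

The unit of data is one ROI time-series matrix per subject per atlas
(timepoints × ROIs), with a binary phenotype. `computeFC()` forms the
Pearson functional-connectivity (FC) matrix; a zero-variance ROI is treated
as a degenerate signal and refused rather than imputed, because a flat
regional signal at this stage almost always indicates an extraction fault.

`knnSparsify()` keeps, for each node, its `K` most similar neighbours and
symmetrises the directed selections by union. Three choices here are
deliberate and exposed:

* **Signed ranking** (`metric = "signed"`, the default): neighbours are
  ranked by the correlation value itself, keeping the strongest *positive*
  couplings, which is the common convention for connectome graphs; ranking
  by magnitude is available as `metric = "absolute"` for sensitivity
  analyses.
* **Union symmetrisation** guarantees every node degree ≥ K, so no ROI is
  ever isolated from message passing.
* **Ties at the K-th rank break toward the lower ROI index**, making graph
  construction bit-reproducible across platforms.

`K = 15` is the default sparsity: on 116-246-node connectomes it yields
sparsely connected graphs, and performance in this family of models is
known to be stable around that value. No Fisher z-transform is applied; raw
correlations serve as both edge weights and features. Node features are the
FC row profiles, so each node carries its whole-brain connectivity
fingerprint and the feature dimension equals the atlas ROI count — which is
what makes the per-atlas encoders genuinely multi-scale.

## The structure-aware encoder

Each atlas has its own encoder: an input projection to `hidden_dim`
followed by `n_layers = 3` SAT layers and mean pooling. A SAT layer
computes, for every node, a *structural embedding*: a two-round
message-passing network (sum aggregation, ReLU after the first round) run
over the node's k-hop induced subgraph and read out at the root. Attention
queries and keys come from these structural embeddings while values come
from the raw node states — so two nodes attend to each other according to
the similarity of their local topology, not merely their current features.
Scaled dot-product attention with per-head dimension `hidden_dim / n_heads`,
a residual connection, post-residual layer normalisation, and a ReLU
feed-forward block with dropout complete the layer.

Numerical and structural notes:

* For `k_hops ≥ 2` (with the two-round GNN) the rooted subgraph readout
  equals full-graph propagation, because every walk of length ≤ 2 from the
  root stays inside its 2-hop induced subgraph; the implementation exploits
  this with one shared fast path. `k_hops = 1` genuinely restricts
  second-round messages and is computed per root; `k_hops = 0` removes all
  neighbour terms, and the encoder then *equals* a plain structure-free
  transformer — an identity the test suite checks to 1e-5 against an
  independent dense implementation.
* Edge weights act as multiplicative message coefficients, so FC magnitude
  information survives sparsification; `edge_mode = "binary"` is an
  ablation switch that keeps topology only.
* Attention rows are exact softmax distributions (checked to 1e-6); the
  whole encoder is permutation-equivariant node-wise and
  permutation-invariant after pooling (checked to 1e-5).
* Dropout (`dropout_rate = 0.3`) is active only in training mode; two
  evaluation passes are bit-identical.
* `k_hops = 2` is the default radius: on 116-246-node graphs it balances
  locality against cost, and it is a grid-searchable tunable.
* "Three graph-convolutional layers" is realised as three stacked SAT
  layers, since the SAT layer (containing the subgraph extractor) is the
  model's only graph-convolutional component.
* Parameters initialise from a symmetric uniform fan-in scheme under a
  recorded seed; all stochasticity (initialisation, shuffling, dropout)
  flows through explicitly seeded generators, so training is exactly
  reproducible.

## Lightweight attentional fusion and the classifier

The per-atlas embeddings are projected (per atlas, since encoder inputs
have unequal dimension) to a shared `fusion_dim`, scored by **one shared
affine map** to a scalar each, and softmax-normalised into per-atlas
weights — nonnegative, summing to 1, at a cost linear in the number of
atlases. The shared scorer is the minimal parameter-efficient design
consistent with "directly learned importance weights": identical inputs
provably receive uniform weights, and a single atlas degenerates to weight
1.0. Weights are computed from each subject's own embeddings
(input-dependent attention), so subject-level weights exist and can be
averaged into the per-atlas attention report. The classifier is one hidden
ReLU layer with the global dropout and a 2-unit softmax head; ties at 0.5
resolve toward the control class.

## Training and nested cross-validation

Defaults follow the reference recipe: AdamW (decoupled weight decay 0.01),
learning rate 0.001 cosine-annealed to `min_lr = 0` over all steps, batch
size 8, 200 epochs, label smoothing `eps = 0.1` (the smoothing mass is a
tunable in the default grid since no canonical value exists). A non-finite
loss aborts with the offending epoch; probabilities are floored at 1e-12
inside the loss, with a message, so degenerate confidence cannot produce
infinities silently.

Evaluation is nested stratified cross-validation: outer folds (10 for
large cohorts, 5 for small ones) estimate generalisation; each outer
training set is split into `inner_folds = 3` folds — the smallest
informative inner split at cohort sizes around a hundred — and the grid
configuration with the best mean inner AUC (AUC because it is the headline
metric; accuracy is available via `select_metric`) is retrained on the full
outer training set. Outer-test subjects never touch selection or training;
the disjointness is asserted on every run and the fold assignments can be
persisted for audit. AUC is computed per outer fold by the rank statistic
(half credit for ties) and then averaged — matching mean ± sd reporting —
rather than pooled.

## Interpretability

Per-ROI attention is defined as **received attention mass**: the column
mean of each attention matrix, averaged over heads, layers and training
subjects. Row-stochasticity makes these weights a distribution over ROIs.
Received mass (rather than emitted) is the convention most consistent with
"ROI-specific weights", and the aggregation is isolated in
`attentionMass()` so the definition can be swapped without touching
anything else. Top-k rankings (default k = 10) break ties toward the lower
index.

Edge statistics among the top ROIs use the Welch unequal-variance t-test —
robust to the group-size imbalance typical of clinical cohorts — with
Benjamini-Hochberg correction applied jointly over the tested pairs within
one atlas (each atlas's 45-pair family is its own correction family), and
significance at q < 0.05. Edges flat in both groups are recorded with
p = 1 and flagged. Cross-atlas overlap of top lists uses a region map:
centroid proximity (single-linkage at 10 mm) when centroids exist, an
explicit label map otherwise; unmapped labels are surfaced in an
`unmatched` bucket, never dropped.

## The synthetic cohort generator

`generateCohort()` emulates the structure this pipeline needs from real
data: `n_latent` zero-mean unit-variance Gaussian sources with a
group-dependent correlation matrix, each ROI of each atlas assigned to one
source, and ROI series = source + independent Gaussian noise
(`noise_sd`). Cases differ from controls only on the designated source
pairs (`effect_edges`, shifted by `effect_delta`); if the shift breaks
positive semidefiniteness the matrix is repaired to the nearest valid
correlation matrix by Higham alternating projections (`Matrix::nearPD`,
tolerance 1e-8), and an irreparable shift (repair moving any entry by more
than 0.1) is a parameter error advising a smaller effect.

Two closed forms anchor the tests: the expected FC between ROIs of
different sources is the latent coupling attenuated by
`1 / (1 + noise_sd²)`, and group differences in expected FC appear *only*
on ROI pairs mapped to effect edges.

What the generator does **not** emulate — and hence what passing tests do
not show about real fMRI: temporal autocorrelation and band-limited
spectra (sources are white; Pearson FC is distributionally sufficient for
testing the pipeline, but real BOLD series are band-passed), site and
scanner effects, head-motion artefacts, hemodynamics, missing data, and
label noise. Results on the synthetic benchmark validate the machinery,
not clinical performance.

### The default scenarios

The desk-scale scenarios use three toy atlases of 20/34/42 ROIs over 12
latent sources so the complete nested-CV recovery experiment runs in
minutes on one CPU (a 116/200/246 `standardSimSpec()` exists for slower
runs). The recovery scenario (`recoverySimSpec()`) fixes 60 cases vs 60
controls, 195 timepoints (a typical post-scrubbing run length), baseline
inter-source coupling 0.2, control coupling 0.5 on the single effect edge
(sources 1-2), case shift −0.4 (hypoconnectivity), and noise sd 0.5. The
affected sources load 2+2 ROIs in `toy20`, 3+3 in `toy34` and 8+8 in
`toy42`: the finest atlas is engineered to carry the strongest planted
signal, giving the fusion module a known right answer. The null scenario
is identical with a zero shift.

## Validation experiments and problem sizes

`runRecoveryBenchmark()` runs nested CV (5 outer / 3 inner folds, grid
over `hidden_dim` ∈ {8, 16}) on the recovery scenario, then scores
per-atlas planted-ROI recall in the top-10 attention ranking and counts
the outer folds in which the engineered atlas wins the mean fusion weight.
Ten training epochs per fit are used at this scale: the planted effect is
strong and the loss plateaus well within ten epochs, so longer schedules
only add runtime. `runNullCalibration()` repeats nested CV on null
cohorts over several seeds with a single small configuration (hidden width
8, 2 heads, 6 epochs) — chance-level behaviour does not depend on capacity
or training length. `nullEdgeCalibration()` checks the edge statistics'
false-discovery behaviour on 200 effect-free repetitions of 45 edges.
These are the computations `scripts/acceptance.R` re-runs and reports.

```{r example}
rb <- runRecoveryBenchmark(seed = 1)
rb$meanAcc; rb$recalls; rb$weightWinFraction
```

## Known limitations

* The neural network is pure R; it is comfortably fast at toy-atlas scale
  and usable at 116-246-ROI scale, but it is not a GPU training stack and
  no distributed or early-stopping machinery exists (training length is a
  fixed budget by design).
* The structural-embedding GNN is fixed at two rounds; radii `k_hops > 2`
  therefore change nothing beyond `k = 2` by construction.
* Fusion uses a single shared scorer; richer gated variants would need a
  new scoring head (the simplex contract and tests would carry over).
* Cross-atlas region mapping is only as good as the supplied centroids or
  label map; anatomical claims beyond label bookkeeping are out of scope.
* No multi-site harmonisation: site effects in real cohorts must be
  handled upstream.
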