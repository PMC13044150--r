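# atlasfuse

Multi-atlas, structure-aware graph-transformer classification of brain
functional-connectivity networks, with an interpretability pipeline and a
synthetic multi-atlas cohort generator.

## The problem

Case/control classification from resting-state fMRI usually starts from a
parcellation (atlas) of the brain into regions of interest (ROIs), a
per-subject matrix of Pearson correlations between ROI time series (the
functional connectome), and a classifier on top. Two recurring weaknesses
motivate this package's model:

* a single atlas fixes one spatial scale, although disease effects are
  expressed at several scales (AAL 116 regions, Craddock CC200, Brainnetome
  246 in the classical triplet);
* plain graph neural networks struggle to encode *where in the network's
  topology* a node sits, which is exactly the signal that distinguishes, say,
  prefrontal-temporal hypoconnectivity from noise.

`atlasfuse` implements a classifier that addresses both, together with the
statistics needed to interpret it, for users who work with ROI time-series
tables (one delimited-text matrix per subject per atlas, timepoints × ROIs)
and a binary phenotype.

## The model

For each atlas, the subject's FC matrix `R` (Pearson, unit diagonal) is
sparsified per node to its `K = 15` most similar neighbours (signed
correlation ranking, union symmetrisation, so every node keeps degree ≥ K)
with edge weight `r_ij`, and node features are the FC row profiles
`x_i = R[i, ]`.

Each graph is encoded by a stack of **structure-aware transformer (SAT)
layers**. In a layer, a small two-round message-passing network with sum
aggregation is run over every node's k-hop induced subgraph (default
`k = 2`) and read out at the root, giving a structural embedding `s_i`;
multi-head attention then uses `Q = S W_q`, `K = S W_k` (structure) and
`V = H W_v` (node states):

    attn(i, j) = softmax_j( <q_i, k_j> / sqrt(d_h) )

followed by residual + layer-norm and a feed-forward block (ReLU, dropout
0.3). With `k = 0` the structural embedding degenerates to an MLP of the
node's own features and the encoder provably reduces to a plain transformer
(this is a tested identity). Mean pooling over nodes gives the per-atlas
graph embedding.

**Fusion (LAFF).** Per-atlas embeddings are projected to a shared space and
scored by one shared affine map; a softmax turns the scores into
nonnegative per-atlas weights summing to 1 — linear cost in the number of
atlases, no pairwise query-key interactions — and the fused representation
is their weighted sum, classified by a small ReLU head. The weights are the
interpretable "which atlas mattered" output.

**Training & evaluation.** AdamW, cosine-annealed learning rate from 0.001,
batch size 8, label-smoothed cross-entropy, 200 epochs by default; nested
stratified cross-validation (grid search by inner-fold AUC on the outer
training set only) reporting ACC / SEN / SPE / AUC as mean ± sd over outer
folds.

**Interpretability.** Per-ROI attention weights (received attention mass,
averaged over heads, layers and training subjects), top-10 ROI rankings per
atlas, cross-atlas overlap of top regions, and Welch two-sample t-tests on
FC edges among top ROIs with Benjamini-Hochberg correction at q < 0.05.

## Worked example

A complete desk-scale analysis on a synthetic cohort with a planted
hypoconnectivity effect (sources 1-2 decoupled in cases, `Δρ = -0.4`,
noise sd 0.5, 60 cases / 60 controls, three toy atlases of 20/34/42 ROIs).
`runRecoveryBenchmark()` simulates the cohort, builds the graphs, runs
nested CV (5 outer / 3 inner folds, grid over the encoder width) and scores
the interpretability outputs against the known planted ROIs:

```r
library(atlasfuse)

rb <- runRecoveryBenchmark(seed = 1)
print(rb$cv)
#> Nested cross-validation: 5 outer folds
#>   ACC: 1.0000 +/- 0.0000
#>   SEN: 1.0000 +/- 0.0000
#>   SPE: 1.0000 +/- 0.0000
#>   AUC: 1.0000 +/- 0.0000

round(colMeans(rb$cv$atlasWeights), 4)
#>  toy20  toy34  toy42
#> 0.2002 0.2052 0.5946

round(rb$recalls, 4)
#>  toy20  toy34  toy42
#> 1.0000 0.8333 1.0000
rb$weightWinFraction
#> [1] 1
```

The planted effect is strong, so the classifier separates the groups
perfectly; the fusion weights concentrate on `toy42` — the atlas engineered
to carry the strongest planted signal (16 of its 42 ROIs load on the
affected sources) — which wins the mean fusion weight in all five outer
folds; and the planted ROI sets are recovered inside the top-10 attention
rankings (recall 1.0 / 0.83 / 1.0). Edge statistics on a top-10 subset
(`discriminativeEdges()`) then flag the case-control FC differences at FDR
q < 0.05, and `crossAtlasOverlap()` groups the per-atlas top lists into
regions shared by 3, 2 or 1 atlases.

Real data enter through `loadCohort(timeseries_dir, phenotype_csv,
atlases)`; `writeCohort()` emits the same layout, and
`inst/cli/atlasfuse.R` wraps simulate / train / evaluate for shell use.

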