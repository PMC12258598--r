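---
title: "Inferring directed cell-cell communication with orthogonally coupled graph autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring directed cell-cell communication with orthogonally coupled graph autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoccc)
```

## The model

Spatial transcriptomics measures a gene expression matrix
$X \in \mathbb{R}^{m \times n}$ ($m$ genes, $n$ cells or spots) together
with a 2-D position for every cell. `orthoccc` turns these measurements
into a weighted, **directed** cell-cell communication (CCC) network under
two assumptions: neighboring cells are more likely to interact than
distant ones, and communication is carried by ligand-receptor (LR)
signaling, so the expression of an LR gene pair across a cell pair is
evidence for a directed sender-to-receiver edge.

Two graphs encode these assumptions:

* the **spatial graph** $A_c$ ($n \times n$, undirected): cells are
  adjacent when their Euclidean distance is *strictly below* a threshold.
  The threshold is chosen by `select_distance_threshold()` as the smallest
  candidate under which more than 80% of cells have at least three
  neighbors, reflecting that most cells in a two-dimensional tissue touch
  several adjacent cells. Ties at exactly the threshold are excluded so
  results are exactly reproducible from the stated rule.
* the **gene graph** $A_g$ ($m \times m$, directed ligand row to receptor
  column), built from a CellChatDB-style interaction table. Multimeric
  complexes are expanded to all ordered subunit pairs, and an edge
  requires both genes to be expressed in the dataset (nonzero in at least
  `min_cells_expressing` cells, default 1). We read "both genes
  simultaneously expressed" as this dataset-level gate per gene, not as
  co-expression within single cells; the stricter co-cellular reading
  would interact badly with dropout and is not what interaction databases
  assume.

Each graph drives a **variational directed graph autoencoder**. The
encoder is a two-layer graph convolutional network
$\mathrm{GCN}(A, X) = \tilde{A}\,\mathrm{ReLU}(\tilde{A} X W_0) W_1$ with
$\tilde{A} = D_{out}^{-1}(A + I)$, the mean and log-standard-deviation
heads sharing $W_0$. Each node receives a Gaussian posterior
$q(z_i) = \mathcal{N}(\mu_i, \mathrm{diag}(\sigma_i^2))$ over a
$d$-dimensional code. The graph decoder splits each code into a source
half and a target half and sets
$p(\hat{A}_{ij} = 1) = \sigma(\langle z_i^{(s)}, z_j^{(t)}\rangle)$: even
though the spatial graph is symmetric, the decoder is free to emit an
asymmetric $\hat{A}_c$, and this is precisely how an undirected proximity
graph becomes a directed communication network. A separate two-layer dense
decoder (ReLU hidden, linear output) reconstructs each node's expression
profile from the same code. We leave the output linear rather than
clamping it nonnegative: the reconstruction enters the objective only
through a squared error and a cosine similarity, both of which are
well-behaved for small negative values, and a ReLU output would zero
gradients for under-predicted entries early in training.

## The objective

Training minimizes

$$
L = \underbrace{(L_{A_g} + \beta\,KL_g + L_{X_g})}_{\text{gene level}}
  + \underbrace{(L_{A_c} + \beta\,KL_c + L_{X_c})}_{\text{cell level}}
  + \underbrace{L_{orth}}_{\text{coupling}},
$$

the minimization form of two negated ELBOs plus reconstruction errors:
$L_{A}$ is a class-weighted Bernoulli cross-entropy on all ordered node
pairs, $L_X = \frac{1}{mn}\lVert X - \hat{X}\rVert_F^2$, and $L_{orth}$
is the mean of $(S - I)^2$ where $S_{ij}$ is the cosine similarity
between cell $i$'s reconstruction from the cell-level decoder and cell
$j$'s reconstruction from the gene-level decoder. Driving $S$ toward the
identity couples the two otherwise independent autoencoders: each cell's
two reconstructions must agree while staying distinguishable from other
cells. Zero-norm reconstruction columns get similarity 0 rather than NaN;
this only matters for degenerate reconstructions.

Numerical and scaling choices that matter:

* **Class weighting.** Spatial graphs are sparse, so positives are
  up-weighted by $(N^2 - E)/E$ and the term scaled by $N^2/(2(N^2 - E))$
  — the standard sparse-graph weighting for adjacency cross-entropies.
  Fully empty or complete graphs fall back to unweighted loss.
* **KL scaling.** The KL term enters the objective as the per-node KL
  divided by $N$ (i.e. a $1/N^2$ total scaling, matching what standard
  VGAE implementations effectively use). We first tried a per-node KL
  ($1/N$): the posterior collapses to the prior ($\mu \to 0$,
  $\sigma \to 1$), the decoder emits 0.5 everywhere, and edge recovery is
  at chance, because the KL gradient on $\mu$ is roughly $N$ times the
  per-entry edge gradients. The public `kl_divergence()` helper still
  reports the per-node mean; `train()`'s loss history records the KL at
  objective scale.
* **Logit-space cross-entropy.** Inside training the adjacency
  cross-entropy is computed from logits with `plogis(, log.p = TRUE)`, so
  the loss is smooth and the analytic gradient exact even when logits
  saturate; the exported `graph_reconstruction_loss()` clips
  probabilities at $10^{-7}$ instead, which is the more natural contract
  for a probability-space helper. The two agree away from saturation.
* **Optimization.** All gradients are derived analytically (the package
  contains its own reverse pass; a finite-difference check against it is
  part of the test suite) and driven by Adam, learning rate 0.01, 200
  epochs, one posterior sample per autoencoder per epoch. Initialization
  is Glorot-uniform with a fixed draw order, so a seed pins the entire
  run bit-exactly. Non-finite losses abort with the name of the first
  offending component.
* **Defaults.** Latent dimension $d = 16$ (must be even for the
  source/target split), hidden width 32, $\beta = 1$, coupling weight 1.
  Setting the coupling weight to 0 provably decouples the two
  autoencoders (also a test).

## Inference and downstream analyses

All predictions use the posterior mean ($Z = \mu$, no sampling), making
inference deterministic. `predict_ccc_network()` returns the full
probability matrix plus binary edges at a cutoff (default 0.5 — the
natural threshold for a Bernoulli decoder, but a reporting convention,
not a learned quantity; aggregation always uses the continuous
probabilities, and the binary edges feed only edge counts, impact ratios
and distance histograms). The diagonal is computed like any entry but
excluded from every downstream count and average.

* **Cell-type aggregation**: the strength from type $k$ to type $l$ is
  the mean probability over ordered cell pairs, self-pairs excluded;
  one-cell types have within-type strength 0 by convention. Significance
  comes from permuting the label vector: $p = (1 + \#\{\text{permuted}
  \geq \text{observed}\})/(1 + n_{perm})$, never exactly zero.
* **LR-pair impact**: retrain with one gene-graph edge removed, with the
  same seed and hyperparameters as the reference run so the difference
  isolates the edge, and report the edge-reduction ratio
  $\max(0, (E_{full} - E_{pert})/E_{full})$ over sender-to-receiver
  binary edges; ranking is by ratio, ties broken lexicographically,
  dense ranks, top 20 by default.
* **Gene sensitivity**: zero-mask (or shuffle) one gene's row, rerun
  inference only, and report the absolute change in average precision of
  recovering $A_c$'s edges. Re-inference rather than retraining keeps the
  score deterministic and the full per-gene scan cheap; retraining per
  gene would fold optimization noise into a quantity meant to measure the
  gene's contribution.
* **Robustness**: delete a fraction of spatial edges (or add fake ones,
  sampled from non-edges, never duplicating existing edges or the
  diagonal), retrain, and score an AUC over equal-sized positive and
  negative candidate sets. Two references exist because the protocol has
  two readings: scoring against the reference run's *predictions*
  (`compare = "predictions"`, the default — a denoising view) or against
  the *held-out deleted edges* (`compare = "heldout"` — an edge-recovery
  view). Both are exposed; every replicate's seed derives from
  `base_seed` and is returned.
* **Spectral clustering** of $(\hat{A}_c + \hat{A}_c^T)/2$ is a thin
  wrapper over the normalized-affinity eigendecomposition plus k-means;
  `k = n` degenerates to one cell per cluster by construction.

## The synthetic data generator

`generate_dataset()` emulates exactly the statistical structure the model
assumes: cell types are spatial Gaussian blobs (so type-pair communication
correlates with proximity), a fixed minority (default 25%) of ordered
type pairs is designated communicating, each carried by one LR gene pair,
and every within-radius sender/receiver pair of a communicating type pair
over-expresses the ligand (sender) and receptor (receiver) genes by a
factor $1 + s$ on top of lognormal multiplicative background noise
(per-gene base means uniform on $[0.5, 2]$, dispersion 0.3). Defaults —
200 cells, 60 genes, 4 types, 10 LR pairs, domain 1000, radius 150,
$s = 5$ — give a few hundred spatial edges and a co-expression signal
strong enough that a naive ligand-times-receptor score separates truth
edges from same-radius non-edges with AUC above 0.9, i.e. the dataset is
learnable in principle. The generator is a pure function of its
parameters including the seed.

What it deliberately does **not** emulate: platform artifacts (optical
crowding, spot mixtures, segmentation errors), count statistics
(zero inflation, library-size variation), 3-D geometry, or signaling that
is not proximity-driven. Tests passing on these data therefore show that
the method recovers the structure it models, under its own assumptions —
not that it resolves real-platform noise.

## Problem sizes and runtime

The shipped checks run at the default 200-cell scale: full training takes
a few seconds on one CPU, the edge-removal protocol (four deletion
ratios, five replicates each) about a minute, and the complete test suite
under two minutes. The robustness repeat count defaults to 30, the
conventional choice for this protocol; the bundled checks use 5
replicates, which is enough to pin medians at this problem size.

## Known limitations

* Whole-graph training only: no minibatching, so memory grows as
  $O(n^2)$; datasets beyond a few tens of thousands of cells need a
  different training regime.
* The LR-impact ratio requires one retrain per edge; batch mode reuses
  the reference run but is still linear in the number of edges probed.
* Aggregation assigns each spot a single predominant type label; mixed
  spots are not deconvolved.
* Coordinates are planar Euclidean; units are the caller's
  responsibility and must match the distance threshold (for reference,
  published radius choices for these graphs range from 10 to 300 μm
  depending on platform).
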