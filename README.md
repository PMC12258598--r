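# orthoccc

Inference of weighted, **directed** cell-cell communication (CCC)
networks from spatial transcriptomics data, for computational biologists
who have per-cell (or per-spot) gene expression, 2-D coordinates,
cell-type labels, and a ligand-receptor (LR) interaction table, and want
to know *which cells signal to which* — and which genes and LR pairs
carry that signaling.

## The method

Two graphs summarize the data: a spatial neighbor graph
`A_c` (cells adjacent when their Euclidean distance is below a threshold
chosen so that >80% of cells have ≥3 neighbors) and a directed LR gene
graph `A_g` (ligand → receptor edges from a CellChatDB-style table,
gated on both genes being expressed). Each graph drives a variational
directed graph autoencoder with a two-layer GCN encoder
`GCN(A, X) = Ã ReLU(Ã X W₀) W₁`, `Ã = D_out⁻¹(A + I)`, and a directed
inner-product decoder

```
p(Â_ij = 1 | z_i, z_j) = σ( ⟨ z_i^(s), z_j^(t) ⟩ )
```

where each latent code splits into a source (sender) half and a target
(receiver) half — so the reconstructed `Â_c` is directed even though the
spatial input graph is not. A dense decoder reconstructs expression from
the same codes, and the two autoencoders are coupled by an **orthogonal
loss** `L_orth = mean((S − I)²)`, with `S_ij` the cosine similarity
between cell *i*'s reconstruction from the cell-level model and cell
*j*'s from the gene-level model. The training objective is

```
L = (L_Ag + β·KL_g + L_Xg) + (L_Ac + β·KL_c + L_Xc) + L_orth
```

optimized with Adam over analytically derived gradients (no autodiff
framework; a finite-difference gradient check is part of the test
suite). Downstream, the package provides cell-type aggregation with
label-permutation p-values, LR-pair impact ranking by edge-reduction
ratio (retrain with one LR edge removed, count lost type-to-type
predictions), per-gene sensitivity scores (|ΔAP| of spatial edge
recovery under gene perturbation), an edge-removal / fake-edge
robustness protocol, spectral clustering of the inferred network, and a
synthetic data generator with known ground-truth communication so the
whole pipeline is testable without any download.

## Worked example

```r
library(orthoccc)

ds <- generate_dataset(synth_params(seed = 3))   # 200 cells, 60 genes,
ds                                               # 4 types, 10 LR pairs
#> synthetic_dataset: 60 genes x 200 cells, 4 types, 10 LR pairs, 1907 truth edges

threshold <- select_distance_threshold(ds$coords)
A_c <- build_spatial_graph(ds$coords, threshold)
A_c
#> spatial_graph: 200 cells, 555 undirected edges, threshold 63.4855
A_g <- build_gene_graph(ds$lr_db, ds$expression)
A_g
#> gene_graph: 60 genes, 10 directed LR edges (0 records skipped)

model <- train(ds$expression, A_c, A_g, seed = 1)
model
#> trained_model: 60 genes x 200 cells, d=16, 200 epochs, total loss 2134710.8467 -> 8.4862

net <- predict_ccc_network(model, ds$expression, A_c)
reconstruction_auc(net, A_c, seed = 1)
#> [1] 0.928
```

The trained decoder separates true spatial-communication edges from
non-edges with AUC 0.93. Cell-type-level strengths and permutation
p-values:

```r
permutation_test(net, ds$labels, n_perm = 1000, seed = 1)
#> celltype_comm: 4 types (sender in rows)
#> strength:
#>        T1     T2     T3     T4
#> T1 0.5374 0.1201 0.0942 0.3079
#> T2 0.1338 0.3550 0.1056 0.1669
#> T3 0.0895 0.1635 0.4674 0.3516
#> T4 0.2619 0.1803 0.3437 0.5167
```

with permutation p-values bottoming out at 1/(n_perm+1) = 0.001 for the
strongest pairs (here the within-type and spatially adjacent type pairs —
the strength matrix reads out which types' cells actually sit within
signaling range of each other). Gene-level sensitivity recovers the
planted signal carriers:

```r
scores <- gene_sensitivity_all(model, ds$expression, A_c)
rank_sensitive_genes(scores, 0.1)
#> [1] "G003" "G007" "G006" "G042" "G004" "G005"
sort(ds$signal_genes)
#> [1] "G001" "G002" "G003" "G004" "G005" "G006" "G007" "G008"
```

Five of the six top-ranked genes are true ligand/receptor signal genes.

A command-line front end over the same functions ships at
`inst/cli/orthoccc.R` with subcommands `simulate`, `build-graphs`,
`train`, `infer`, `lr-impact`, `cluster`, `sensitivity` and
`robustness`, reading/writing the TSV formats of the I/O module.

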