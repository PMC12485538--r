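# gule — credibility-graph spectral clustering with adaptive graph cuts

`gule` is an R package for unsupervised clustering and visualization
preparation on data whose classes are defined by *connectivity* rather than
by shape, density or linear separability — interlocking curved manifolds,
nested structures of very different densities, single-cell expression
profiles. It is aimed at analysts who have a feature matrix (rows =
samples), a target number of classes `K`, and no labels.

The method rests on a single principle: nearby points tend to share a
class, and that local consistency can be propagated globally. It is
implemented in two layers, each consisting of

1. **Local extraction** — per-point class-consistent neighborhoods of size
   `kc = k0 + ⌊log2(n/K)⌋` (layer 1) or an adaptive gap-selected size
   (layer 2), with pairwise confidence weights
   `a_ij = 2 / (1 + exp((α γ_ij)² / 2))`, where
   `γ_ij = d(i,j) / max(ω_i, ω_j)` normalizes the distance by the
   neighborhoods' exclusion radii. Pairs with `γ_ij ≤ 1` form a sparse
   symmetric **credibility graph**.
2. **Global propagation** — an adaptive spectral graph cut maximizing
   `Σ_k (Σ_{i,j∈C_k} a_ij) / (Σ_{t∈C_k} d_t^β)` with `β = 1 − s` set from
   the graph's average connection strength `s`, interpolating between the
   normalized cut (`β→1`, sparse graphs) and ratio association (`β→0`,
   dense graphs). The relaxed solution is the top-`K` eigenbasis `U` of
   `D^{−β/2} A D^{−β/2}`, whose rows are the projected points fed to the
   next layer.

Labels are read off a **completely-positive-factorization (CPF) rotation**:
an orthogonal `Q` minimizing `¼‖QQᵀ−I‖² + (K/n)‖(UQ)⁻‖²` rotates `U`
toward its ideal nonnegative Perron basis, and each point takes the class
of its largest-magnitude rotated coordinate — a deterministic alternative
to k-means on the spectral embedding.

The package also provides consensus-based distance-metric selection (mean
pairwise NMI between the labelings different metrics produce), external
indices (ACC by optimal assignment, NMI, ARI), internal indices
(silhouette, neighborhood purity, graph score), coupled distance matrices
for topology-preserving t-SNE/UMAP/MDS embeddings, seeded 2-D benchmark
generators, and numeric diagnostics for the perturbation theory behind the
method (ideal block decomposition, spectral-norm bound, worst-case
mislabel count).

## Worked example

```r
library(gule)

d   <- make_entangled(n = 900, seed = 0)   # three interlocking spiral arms
fit <- gule(d$X, K = 3, seed = 0)
print(fit)
#> Two-layer credibility-graph clustering
#>   n = 900, K = 3, metric = euclidean
#>   layer 1: kc = 13, alpha = 6, s = 0.153, beta = 1.000, gap = 3.885e-07
#>   layer 2: kc = 13, alpha = 2, s = 1.000, beta = 0.000, gap = 299.7
#>   cluster sizes: 300, 300, 300

ev <- evaluate_labels(fit$labels, d$truth)
cat(sprintf("ACC = %.3f, NMI = %.3f, ARI = %.3f\n", ev$acc, ev$nmi, ev$ari))
#> ACC = 1.000, NMI = 1.000, ARI = 1.000
```

Reading the output: the first layer sees a sparse graph (strength
`s = 0.153`), so the cut operates at its normalized-cut limit; the
projection separates the arms, after which the second layer's graph is
near-complete within classes (`s = 1`) and the cut switches to its ratio
association limit with an enormous spectral gap (299.7 vs the fourth
eigenvalue 0.068). All 900 points land in their true arm. `plot(fit)`
shows the data colored by cluster; `plot(fit, "spectrum")` the per-layer
eigenvalue decay; `gule_visualize(fit)` returns 2-D coordinates of the
coupled raw/projected distances.

A thin command-line wrapper over the same functions ships in
`inst/cli/gule.R` with `cluster`, `evaluate`, `visualize`, `synth` and
`diagnose` subcommands.

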