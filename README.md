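# plnmfg

Joint clustering of cells from **paired single-cell multi-omics data**
(RNA + ADT from CITE-seq, or RNA + ATAC) by pseudo-label guided,
graph-constrained collective non-negative matrix factorization.

Single-cell layers disagree in character: ADT panels are small but nearly
dropout-free, RNA and ATAC are high-dimensional and riddled with "false
zeros" from sequencing loss. `plnmfg` is for analysts who want one model
that integrates the layers instead of reducing each separately: all omics
share a single non-negative latent representation, dropout candidates are
recovered by a sparse imputation block, each layer's own k-means clustering
enters as a soft pseudo-label prior, cluster structure is learned inside
the optimization under a cell-graph manifold penalty, and omic weights are
learned on the simplex from each layer's residual cost.

## The model

For omics $X^i \in \mathbb{R}^{d_i\times n}_{\ge 0}$ (cells are columns),
the method minimizes

```math
\sum_{i=1}^{v}\alpha_i^{\gamma}\Big\{\|X^i+S^i-U^iV\|_F^2
+\eta\sum_j u_j\|S^i_{\cdot j}\|_1
+\delta\|Y^i-Q^iV\|_F^2\Big\}
+\beta\|V-CG\|_F^2+\varepsilon\,\mathrm{Tr}(GLG^{\top})
```

over non-negative blocks with $\sum_i\alpha_i=1$: $U^i$ per-omic bases,
$V$ the shared $k\times n$ representation, $S^i$ imputation matrices
supported on detected dropout candidates (weighted by per-cell sequencing
depth $u_j$), $Y^i$ fixed per-omic k-means pseudo-labels with projections
$Q^i$, $C$/$G$ the centroid and relaxed indicator factors of $V$, and
$L = D - A$ the Laplacian of a binary kNN cell graph. Optimization is
alternating block minimization with multiplicative updates (closed forms
for $S$ and $\alpha$); the objective is guaranteed — and enforced at run
time — never to increase. Cluster labels are the column-wise argmax of
$G$. See the methods vignette (`vignettes/plnmfg-methods.Rmd`) for the full
account, parameter guidance, and known limitations.

## A worked example

```r
library(plnmfg)

sim <- simulate_multiomics(sim_preset("tiny", seed = 1))  # 60 cells, RNA+ADT, 3 types
x   <- preprocess_omics(sim$dataset)                      # lognorm RNA, CLR ADT, rescale
fit <- plnmfg(x, c = 3, hp = plnmfg_hyperparameters(seed = 1))
fit
#> plnmfg fit: 60 cells -> 3 clusters
#>   iterations: 50 (converged)
#>   objective: 11.99079
#>   omic weights: 0.2784 0.7216
#>   cluster sizes: 17 23 20

clustering_metrics(fit$labels, sim$truth$labels)
#> $acc 0.883  $ari 0.679  $nmi 0.664  $ami 0.653
```

The printout says the alternating solver converged (relative objective
change below `tol = 1e-5`) after 50 outer iterations; the learned simplex
weights put 72% of the weight on the ADT layer (its residual cost is
lower); and against the simulated ground truth the labels score 88%
optimal-matching accuracy with ARI 0.68 — a deliberately noisy 60-cell
fixture. On the larger simulated presets (`sim_preset("sim1")`,
`sim_preset("sim2")`) with the default separation, recovery is near
perfect (ARI ≈ 0.94–1.0 per replicate).

Real datasets enter through `read_multi_omics()` (Matrix Market + barcode
and feature sidecars, dense CSV, or HDF5), and a thin command-line
front-end wraps the same functions:

```sh
Rscript inst/cli/plnmfg.R simulate --preset sim1 --seed 0 --out data/
Rscript inst/cli/plnmfg.R fit --config run.yaml
Rscript inst/cli/plnmfg.R eval --pred out/labels.csv --truth data/truth.csv
Rscript inst/cli/plnmfg.R sweep --config run.yaml --grid "beta=0.001,0.01,0.1;delta=0.001,0.01,0.1" --out sweep.csv
```

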