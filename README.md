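# tlse — robust geometric embedding of protein–protein interaction networks

Protein–protein interaction (PPI) networks are graphs of proteins
joined by physical interactions. Under the *geometric assumption*,
proteins are points in a latent metric space and interactions join
pairs closer than a threshold — but the connectivity data used to
infer those positions is riddled with false positive and false
negative interactions from high-throughput assays.

`tlse` fits a **t-logistic semantic embedding**: each protein gets
coordinates `z_i` in d dimensions, and a pair's interaction
probability is `F_t(b − ‖z_i − z_j‖²)`, where `F_t` is the two-class
t-exponential link, `b` a learned squared-distance cutoff, and
`t ∈ [1, 2)` the loss parameter. At `t = 1` the negative
log-likelihood is the convex logistic loss; at the default `t = 1.9`
it is a heavy-tailed, *bounded-influence* loss whose gradient
vanishes for hopelessly misfit pairs, so noise edges cannot dominate
the fit. The likelihood is maximised by an alternating scheme — a 1-D
bias update, then a coordinate step along a Laplacian-preconditioned
descent direction with a Wolfe line search — so the objective
decreases monotonically.

Around the estimator the package provides the standard experimental
toolkit for this literature:

* `mdsgeo()` — the classical baseline: shortest-path (hop) distances
  embedded by classical multidimensional scaling.
* `gen_er()`, `gen_erdd()`, `gen_sf()`, `gen_sticky()`,
  `gen_geometric()` — the usual null models (uniform, degree-matched
  stubs, preferential attachment, stickiness index) and a geometric
  generator with known ground-truth coordinates.
* `perturb_network()` / `noise_experiment()` — random edge
  deletion/insertion noise and the fit-under-noise driver.
* `orbit_counts()` / `gdd_agreement()` — graphlet-degree-distribution
  agreement between networks (graphlets up to 4 nodes by default, 5
  behind a flag).
* `roc_auc()`, `conditional_densities()`, `rank_edges()` — recovery
  ROC/AUC, conditional distance densities, and edge-reliability
  ranking.

## Worked example

```r
library(tlse)

# synthetic ground truth: 300 points in the plane, 1200 closest pairs
g    <- gen_geometric(300, d_true = 2, m_target = 1200, seed = 0)
comp <- graph_components(g$net)[[1]]     # embed the giant component

fit <- tlse(comp, dim = 2, t = 1.9, seed = 0)
fit
#> t-LSE embedding (t = 1.9, d = 2)
#>   network: 299 nodes, 1200 edges
#>   objective: 6.69728 after 500 iterations (max_iter)
#>   bias (squared-distance cutoff): 769.2

# how well do embedding distances recover the true edges?
ev <- roc_auc(score_pairs(fit, comp$edges),
              score_pairs(fit, all_non_edges(comp)))
ev
#> ROC evaluation: 1200 interacting vs 43351 non-interacting pairs
#>   AUC (rank-based): 1.0000
#>   best Youden point: threshold 28.84, sens 1.000, spec 1.000

# the MDS-GEO baseline on the same component
base <- mdsgeo(comp, dim = 2)
roc_auc(score_pairs(base, comp$edges),
        score_pairs(base, all_non_edges(comp)))$auc
#> [1] 0.9964462
```

An AUC of 1.0 means the fitted distances rank (essentially) every true
interaction ahead of every non-interaction; the bias `b` is the
squared distance at which the fitted interaction probability crosses
1/2. On clean geometry both methods do well; the difference appears
under noise — rewire 10% of edges and refit:

```r
tab <- noise_experiment(comp, levels = 0.10, replicates = 5, dim = 2,
                        seed = 1,
                        control = tlse_control(max_iter = 150,
                                               exact_negatives = FALSE))
tab[, c("level", "method", "mean_auc", "sd_auc")]
#>   level    method  mean_auc      sd_auc
#> 1   0.1    mdsgeo 0.9048744 0.008880064
#> 2   0.1 tlse_t1.0 0.9532208 0.002325700
#> 3   0.1 tlse_t1.9 0.9633391 0.004251109
```

The heavy-tailed loss (`t = 1.9`) retains the most recovery power
against the *clean* labels, the convex logistic (`t = 1.0`) is next,
and the MDS baseline — whose shortest-path distances are corrupted
directly by the noise — trails. Ranking a noisy network's edges by
embedding distance (`rank_edges(fit, net)`) turns this into an
edge-reliability screen: planted false edges concentrate at the bottom
of the ranking.

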