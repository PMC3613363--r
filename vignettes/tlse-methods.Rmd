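---
title: "Robust geometric embedding of PPI networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust geometric embedding of PPI networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlse)
```

## The geometric model

Protein–protein interaction (PPI) data arrive as an undirected graph:
proteins are nodes, physical interactions are edges.  The geometric
assumption holds that proteins occupy positions in a latent metric
space — abstract axes of binding surfaces, modifications, localisation
— and that interactions join pairs that are close.  `tlse()` learns
such positions from connectivity alone.

Each node $i$ receives coordinates $z_i \in \mathbb{R}^d$ and the model
scores a pair through the margin

$$\xi_{ij} = b - \lVert z_i - z_j \rVert^2,$$

with a single global bias $b$ acting as a squared-distance cutoff.  The
interaction probability is $F_t(\xi_{ij})$ and the non-interaction
probability $F_t(-\xi_{ij})$, where $F_t$ is the two-class
t-exponential link described below; the two probabilities sum to one by
construction, and $F_t(0) = \tfrac12$, so $b$ is exactly the squared
distance at which a pair is as likely interacting as not.  The squared
(rather than plain) distance is used inside the link because it makes
the stationarity condition of the likelihood a weighted-average fixed
point: at an optimum, each $z_i$ is the weighted mean of its partners'
positions, with attractive weights on edges and repulsive weights on
non-edges.

Fitting minimises the negative log-likelihood

$$L(Z, b) = \sum_{(i,j) \in E} \ell_t(\xi_{ij})
          + w \sum_{(i,j) \notin E} \ell_t(-\xi_{ij}),$$

where $\ell_t(u) = -\log F_t(u)$ and $w$ reweights a sampled set of
non-edges (see *Negative pairs* below).

## The t-logistic loss

High-throughput interaction data are noisy: a sizeable fraction of
edges are spurious and many true interactions are missing.  A convex
loss such as the logistic is dominated by exactly those pairs the model
fits worst — its gradient magnitude grows monotonically as a pair's
margin deteriorates — so false edges pull hardest on the solution.

The t-exponential family replaces $\exp$ by
$\exp_t(x) = [1 + (1-t)x]_+^{1/(1-t)}$ for $t \in (1, 2)$, which decays
*polynomially* as $x \to -\infty$.  The two-class link is

$$F_t(u) = \exp_t\!\big(u/2 - G_t(u)\big),$$

where the normaliser $G_t(u)$ is the unique solution of
$\exp_t(u/2 - g) + \exp_t(-u/2 - g) = 1$; it has no closed form for
$t > 1$ and is solved numerically (below).  The loss is the ordinary
negative logarithm of that probability, so at $t = 1$ everything
reduces exactly to the logistic loss $\log(1 + e^{-u})$; the test-suite
asserts this limit to $10^{-10}$.

The payoff is the derivative.  For $t = 1$, $|\ell'|$ saturates at 1 as
the margin worsens; for $t = 1.9$ it peaks and then *decreases*, so a
hopelessly misfit pair — typically a noise edge — has vanishing
influence on the gradient.  The derivative is obtained by implicit
differentiation of the normaliser,
$\ell_t'(u) = -p^{t-1} q^t / (p^t + q^t)$ with $p = F_t(u)$,
$q = F_t(-u)$; because this identity is derived rather than quoted, it
is unit-tested against central finite differences.

`t = 1.9` is the default: the loss family is essentially saturated in
its robustness behaviour as $t \to 2$, and values in $(1.9, 2)$ are
numerically indistinguishable in their effect.

## Computing the normaliser

$G_t(u)$ is bracketed below by $|u|/2$.  The residual is convex and
strictly decreasing in $g$, so a Newton iteration started at the
bracket converges monotonically; the implementation (a small C++
kernel, since this is the innermost loop of every objective and
gradient evaluation) starts from the first-order guess
$|u|/2 + \exp_t(-|u|)$, stops at a residual tolerance of $10^{-12}$,
and also accepts when no representable improvement remains — for
margins of magnitude $10^5$ the residual floor is set by the spacing of
doubles near $g \approx |u|/2$, around $10^{-11}$, which is the honest
machine-precision answer.  A bisection safeguard with a doubling
bracket backs the Newton stage.

## The optimiser

The loss for $t > 1$ is non-convex, and joint gradient descent on
$(Z, b)$ proved slow and prone to poor local minima.  The fit
alternates instead:

1. **Bias step.** With $Z$ fixed, $b$ is a smooth one-dimensional
   problem; it is driven to local optimality by backtracking gradient
   descent (the pair distances are cached, so each inner evaluation is
   one vectorised loss pass).
2. **Coordinate step.** With $b$ fixed, one update of $Z$ along a
   preconditioned direction $D = -M^{-1} \nabla_Z L$ with a weak-Wolfe
   line search ($c_1 = 10^{-4}$, $c_2 = 0.9$).

The default preconditioner $M$ is the graph Laplacian of the
*attractive* (edge) mixing coefficients plus a ridge $\lambda I$
($\lambda = 10^{-4}$), solved sparsely.  This is the natural linear
system suggested by the weighted-average fixed point, and it is
symmetric positive definite by construction, so $\langle D, \nabla
\rangle < 0$ whenever the gradient is non-zero — the descent property
is also checked explicitly at run time, with a fall back to the raw
negative gradient.  A Jacobi alternative (`precond = "diagonal"`,
$M = \mathrm{diag}(\sum_j |W_{ij}| + \lambda)$) is retained: it is
cheaper per step but needs many more steps — on the reference recovery
experiment below it stalls at a visibly worse optimum — and an
`"identity"` option gives plain gradient descent for comparison.

Because every accepted step decreases the objective (Armijo) and the
bias step only ever decreases it, the objective trace is monotone
non-increasing; the suite asserts this on every fitted instance.
Iteration stops when the relative objective change drops below
$10^{-6}$ or after `max_iter = 500` outer iterations.

**Initialisation.** The default is a warm start from the MDS-GEO
baseline (below) plus a small Gaussian jitter.  With a random Gaussian
start the non-convex $t = 1.9$ objective frequently converges to local
optima whose edge-recovery quality falls below the *baseline itself*,
which would make the adaptive model pointless; a globally arranged
spectral start is the standard remedy for non-convex embedding
objectives, and with it the fit consistently improves on its
initialiser.  `init = "random"` remains available and is what the
restart mechanism (`restarts`) perturbs.

**Negative pairs.** Using every non-edge is quadratic in $n$.  By
default the exact complement is used when the network has at most
250{,}000 non-edges (roughly $n \lesssim 700$ for sparse graphs);
beyond that, $5\,|E|$ non-edges are sampled once per fit and reweighted
by (#non-edges / #sampled), making the sampled objective an unbiased
estimate of the full one.  Sampling once per fit — not per iteration —
keeps the minimised objective fixed so that monotone descent is
well-defined.  On small networks the exact objective matters: with
sampled negatives the optimiser can park unsampled non-edge pairs at
small distances without penalty, which measurably hurts whole-graph
recovery.

## The MDS-GEO baseline

The classical geometric approach embeds the hop-distance matrix
(breadth-first shortest paths) by Torgerson's classical MDS:
double-centre the squared distances, eigendecompose, scale the top-$d$
eigenvectors by root eigenvalues.  Components must be embedded
separately (hop distance is infinite across components); the
perturbation driver, which must embed fragmented graphs in one frame,
optionally imputes unreachable distances as (max finite hop + 1).
Eigenvector signs are fixed by making each column's largest-magnitude
entry positive, so results are deterministic.  For score compatibility
with `tlse()` fits, an `mdsgeo()` object carries a bias chosen to
maximise Youden's J on the training edges.

## Null models and synthetic ground truth

The generators reproduce the standard comparison set, each consuming
exactly the information its model is allowed:

* **ER** — `gen_er(n, m)`: exactly $m$ uniform edges.
* **ER-DD** — `gen_erdd(reference)`: stub matching of the reference
  degree sequence; self-loops and duplicates are rejected.  Stub
  pairing can dead-end with a few stranded stubs (the probability grows
  with density, roughly the chance the last stubs land on an existing
  edge); the construction restarts — up to 10 seeded attempts — until a
  residue-free pairing is found, i.e. the distribution conditioned on
  success.  Any remaining residue is reported.
* **SF** — `gen_sf(n, m)`: Barabási–Albert preferential attachment from
  a short path seed; the per-node attachment count is randomised
  between the floor and ceiling of the required average so the expected
  edge count matches `m`.
* **Sticky** — `gen_sticky(reference)`: stickiness index
  $\theta_i = \deg(i)/\sqrt{\sum_k \deg(k)}$, pair probability
  $\min(1, \theta_i\theta_j)$ (clips counted).
* **GEO** — `gen_geometric(n, d, m)`: uniform points in the unit cube,
  the $m$ closest pairs connected (radius ties broken by pair index).
  The generator returns its coordinates, giving a perfect-recovery
  oracle: scoring pairs by true distances yields AUC 1 by construction.

The geometric generator is the synthetic stand-in for real PPI
networks in all recovery experiments.  The reference condition used
throughout the acceptance experiments is $n = 300$, $d_{\text{true}} =
2$, mean degree 8 ($m = 1200$) — comparable in density to curated
interactomes, whose average degree is about 4–7 — with the largest
connected component embedded, since the protocol treats components
separately.  What these graphs deliberately lack is the degree
heterogeneity, clustering structure and assay-specific noise of real
interactomes: passing recovery tests here demonstrates that the
estimator recovers latent geometry under its own assumptions, not that
it resolves any particular organism's interactome.

**Noise model.** `perturb_network(net, frac)` deletes
$\lfloor\text{frac}\cdot|E|\rfloor$ random edges and inserts equally
many random non-edges — simulated false negatives and false positives
— conserving $|E|$ and the node set.  The robustness experiment
(`noise_experiment()`) fits embeddings to perturbed graphs and scores
them against the *clean* graph's edges and non-edges; levels 5%, 10%
and 25% with 5 replicates are the reference conditions.  The
experiment's fits use the sampled-negative objective and a 150-iteration
cap: at $15 \times 2$ t-LSE fits plus baselines per run this is the
problem size that keeps the experiment interactive, and the AUC
ordering is stable well before the cap.

## Graphlets and GDD agreement

A graphlet is a small connected induced subgraph; an orbit is an
automorphism class of its node positions (the two ends of a 3-path are
one orbit, its middle another).  `orbit_counts()` enumerates connected
induced subgraphs exactly once (the ESU scheme) and classifies each
occurrence: sizes 2–3 in closed form, size 4 by within-subgraph degrees
(which determine the orbit uniquely for all six 4-node graphlets), and
size 5 — 21 graphlet types, 58 orbits, enabled with `max_size = 5` —
via a lookup table built at first use from an exhaustive atlas of
5-node graphs, with orbits determined by brute-force automorphisms and
keyed by Weisfeiler–Lehman colour signatures (the build asserts the
signatures separate both classes and orbits, so a collision cannot pass
silently).  Orbits 0–14 follow the standard numbering; size-5 orbit ids
are deterministic but internal, which is immaterial to the agreement
measure since it is invariant to orbit relabelling.

The graphlet degree distribution (GDD) of orbit $j$ is the histogram
over $k \ge 1$ of nodes touching orbit $j$ exactly $k$ times, scaled by
$1/k$ and normalised to unit mass — the scaling makes the profile
invariant to disjoint duplication of the graph.  Per-orbit agreement is
$1 - \tfrac{1}{\sqrt 2}\lVert N^A_j - N^B_j \rVert_2$ over the union
support (the $\sqrt 2$ bound is attained by disjointly supported unit
vectors, so the value lies in $[0,1]$), and the overall agreement
averages the per-orbit values arithmetically by default (a geometric
mean is offered); orbits empty in both networks are excluded rather
than counted as trivially perfect.  The default `max_size = 4` keeps
desk-scale comparisons fast; correctness of both sizes is tested
against a brute-force subgraph-isomorphism oracle.

## Evaluation conventions

Pairs are scored by embedding distance, lower meaning more likely to
interact.  Sensitivity and specificity come from a threshold sweep
(“interacting if distance < threshold”) over all distinct scores plus
endpoints, but the reported AUC is rank-based — the probability that an
edge scores below a non-edge, ties counted half — which is exact and
free of grid artifacts; a random predictor gives 0.5 under this
convention, and the sweep is still emitted for plotting.  Conditional
densities $p(\text{distance} \mid \text{interaction})$ and
$p(\text{distance} \mid \text{non-interaction})$ use Gaussian kernels
with Silverman's rule on a shared grid, renormalised to integrate to
one.  Edge reliability ranking (`rank_edges()`) orders a network's
edges by distance with deterministic lexicographic tie-breaks; its
top-$q$ slice is the coverage sub-network used in reliability
assessment.  Evaluation negatives are every non-edge up to 500k pairs,
a seeded sample of $10|E|$ beyond that.

## Numerical and design notes

* All randomness flows through explicit integer seeds; generators and
  fits restore the caller's RNG state.  One master seed derives
  independent sub-streams for initialisation and negative sampling.
* `simulate()` on a fitted embedding draws each pair independently with
  its fitted probability — the generative direction of the model, used
  for model-fit comparisons against the null generators.
* Degenerate inputs: empty graphs are rejected by the fitters;
  edgeless orbits yield empty GDD profiles; a stalled line search
  returns the best iterate with a flag rather than looping.
* Test-suite problem sizes are deliberately modest (tens to a few
  hundred nodes, the reference condition above for the acceptance
  experiments); the method itself has no such limit, though
  `orbit_counts()` and exact negatives are desk-scale by design.

## Known limitations

* The geometric null model exercises none of the degree heterogeneity
  of scale-free-like interactomes; conclusions about robustness
  transfer to real data only qualitatively.
* One global bias $b$ means a single interaction radius for the whole
  proteome; per-node biases (sticky-like propensities) are out of
  scope.
* The 5-node orbit numbering is internal, so per-orbit size-5 output
  should be compared within this package only.
* GO-annotation-based functional coherence evaluation requires external
  annotation data and is intentionally not included; the edge-ranking
  primitive it would consume is.
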