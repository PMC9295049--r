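---
title: "Graph-based mixture modelling of local false discovery rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based mixture modelling of local false discovery rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphlfdr)
```

## The testing problem

Many large-scale two-group comparisons attach one test to every vertex of a
known graph: voxels of a brain image connected by spatial adjacency, genomic
loci along a chromosome, sensors in a network.  Mass-univariate testing
(per-vertex t-tests followed by multiplicity correction) ignores the graph,
and when true effects are weak but spatially coherent it can be badly
underpowered.

`graphlfdr` implements an empirical-Bayes mixture model that exploits the
graph.  The central modelling object is a *graph-respecting partition*: a
partition of the vertices in which every block induces a connected subgraph.
Group means are constrained to be constant on blocks, and each block either
differs between the two groups (shifted) or not (null).  Averaging over all
such partitions and shift states yields, for every vertex $v$, a local false
discovery rate
$$
l_v = P(H_{0,v} \mid X, Y)
    = \sum_{\Psi, \Delta} (1 - \Delta_{k(v)})\, P(\Delta, \Psi \mid X, Y),
$$
the posterior probability that the block containing $v$ is unshifted.  A
discovery list $\{v : l_v \le c\}$ then has conditional expected type-I
proportion bounded by $c$, and the data-computable *controlled FDR* of any
list is the mean of its $l_v$.

Restricting to graph-respecting partitions is a dimension constraint, and it
is severe: the 3&times;3 lattice admits only 1434 of the 21147 set partitions
of nine objects.  Under the uniform prior over those 1434 partitions the
median number of blocks is 4, and the block containing the first vertex in
enumeration order has at most three vertices with probability 0.71 (for the
window's geometric centre the probability is 0.60).  The prior therefore
insulates the vertex on test from data far away in the window.

## Model and computation

Within a local subgraph of $N$ vertices the sampling model is Gaussian with
unrestricted group covariance matrices,
$X_m \sim \mathcal N(\mu_X, U)$ and $Y_r \sim \mathcal N(\mu_Y, W)$,
with conjugate inverse-Wishart priors $U \sim \mathcal{IW}(A, \mathrm{df})$,
$W \sim \mathcal{IW}(B, \mathrm{df})$.  The covariances integrate out
analytically:
$$
f(X, Y \mid \mu_X, \mu_Y) \;=\; C\,
  \frac{|A|^{\mathrm{df}/2}\,|B|^{\mathrm{df}/2}}
       {|\tilde A|^{(\mathrm{df}+M_X)/2}\,|\tilde B|^{(\mathrm{df}+M_Y)/2}},
\qquad
\tilde A = A + (M_X - 1) S_1 + M_X (\bar X - \mu_X)(\bar X - \mu_X)^{\!\top},
$$
with $\tilde B$ analogous.  The likelihood deliberately allows arbitrary
covariance between vertices and does **not** factor over blocks (no
product-partition assumption).  `log_density_given_means()` implements the
constant $C$ in full (multivariate-gamma form), so the value is an absolute
log density; the unit tests exploit this by checking it against adaptive
quadrature of the Normal &times; inverse-Wishart model at $N = 1$ and
$N = 2$.

Block base means get independent $\mathcal N(\mu_0, \tau^2)$ priors, shifts
of flagged blocks $\mathcal N(\delta_0, \sigma^2)$, and these free means are
integrated by Laplace approximation around the posterior mode
(`laplace_log_marginal()`).  The discrete prior takes $P(\Psi) \propto 1$
over the enumerated graph-respecting partitions, with i.i.d. Bernoulli block
states: each block is null with probability $p_0$.

Two implementations of the Laplace step coexist deliberately.  The reference
R path follows the generic recipe — quasi-Newton search with
finite-difference derivatives — and is the one validated against Gauss-Hermite
quadrature of the full integrals.  The compiled path used by the
whole-lattice driver exploits the structure of the problem: because
$\tilde A$ differs from the fixed $A_0 = A + (M_X-1)S_1$ by a rank-one
update, the matrix determinant lemma collapses the log density to
$\mathrm{const} - c_X \log(1 + M_X q_X) - c_Y \log(1 + M_Y q_Y)$ with
quadratic forms $q$ that aggregate to block level, so each configuration is
maximized by a damped Newton iteration with closed-form gradient and Hessian
in at most $2K$ dimensions.  The two paths agree to about $10^{-6}$ in log
marginal likelihood; the test suite asserts both this agreement and the
quadrature match.

### Whole-lattice deployment

Enumerating partitions of a whole image is impossible, so `graphmm()`
deploys the model *locally*: for every vertex it extracts a small
neighbourhood subgraph, runs the full mixture there, and keeps the posterior
null probability of the centre only.  Three neighbourhoods are supported:

| kind         | window                          | vertices | partitions |
|--------------|---------------------------------|----------|------------|
| `lattice3x3` | in-slice 3&times;3 window       | &le; 9   | 1434       |
| `star2d`     | centre + 4 in-slice neighbours  | &le; 5   | 16         |
| `star3d`     | centre + 6 neighbours           | &le; 7   | 64         |

Border windows are clipped, never padded; the model runs on whatever
connected subgraph remains, with the scale matrices $A$, $B$ subset to the
matching principal submatrices.  Vertices whose computation fails are scored
conservatively with $l_v = 1$ rather than dropped.  Vertex computations are
mutually independent, so results do not depend on traversal order.

## Hyperparameters

All hyperparameters are estimated once from the whole lattice
(`estimate_hyperparams()`), then shared by every local model:

* $\mu_0$, $\tau^2$ — mean and variance across vertices of the pooled
  per-vertex sample means ($\tau^2$ floored at $10^{-6}$).
* $\delta_0 = 0$ — symmetric two-sided testing; configurable.
* $\sigma^2$ — the model defines $\sigma^2$ as the shift variance *given*
  a block is non-null, while the observed vertex differences mix null and
  non-null vertices: $\mathrm{Var}_v(\bar Y_v - \bar X_v) \approx
  (1 - p_0)\sigma^2 + \text{sampling variance}$ when $\delta_0 = 0$.  The
  estimator therefore subtracts the average sampling variance and rescales
  by the estimated non-null fraction $1 - \hat p_0$ (floored at $10^{-6}$).
  Skipping the rescaling tightens the shift prior by the non-null fraction,
  which in our experiments made boundary vertices overconfident: merging a
  null vertex into a shifted neighbour block becomes artificially cheap
  because the merged block's attenuated shift sits closer to the centre of
  an over-narrow prior.
* $\mathrm{df} = N_{\mathrm{win}} + 2$ — the smallest value at which the
  inverse-Wishart has a finite mean, keeping the prior as diffuse as
  possible; $A = (\mathrm{df} - N_{\mathrm{win}} - 1)\hat\Sigma_X$ centres
  the prior on $\hat\Sigma_X$, the across-window average local sample
  covariance shrunk 50% toward its diagonal (likewise $B$).
* $p_0$ — Storey's estimator at $\lambda = 0.5$ applied to per-vertex Welch
  t-test p-values.  We use the plug-in $p_0$ at block level even though it
  estimates a vertex-level null fraction; under block-level Bernoulli truth
  the two coincide in expectation.

Every sub-estimator choice (floors, $\lambda$, shrinkage fraction,
$\delta_0$) is an exposed argument.  Preprocessing helpers mirror the usual
imaging pipeline: `low_variance_filter()` removes near-constant vertices and
`normal_scores()` converts each vertex to rank-based normal scores
(midranks, $\Phi^{-1}((r - 0.5)/M)$), which makes the Gaussian sampling
model a transformation-scale assumption rather than a raw-data one.

## The two-pair toy system

The blocking phenomenon in its smallest form: pairs of variables measured in
two conditions, $H_0: \mu_{X_1} = \mu_{Y_1}$ with marginal probability
$p_0$, and with probability $p_{\mathrm{block}}$ the second variable shares
both latent means with the first.  All latent means are standard normal and
observations add $\mathcal N(0, \sigma^2)$ noise.  `toy_lfdr1()` scores the
test with the first pair only; `toy_lfdr2()` mixes over the four
(null &times; blocked) states with 4-variate normal components whose
covariances $\sigma^2 I + ZZ^{\!\top}$ are built from explicit shared-mean
incidence matrices $Z$ — no hand-entered covariance matrices, so the
construction generalizes and cannot drift out of sync with the state
definitions.  When $p_{\mathrm{block}} = 0$ the two scores coincide exactly;
when blocking is present, ranking by `toy_lfdr2` yields a longer list at any
matched FDR.

The mis-specification experiment re-scores data generated under one blocking
rate with a different assumed rate.  Underestimating the rate
(under-regularizing) keeps the realized FDR below its nominal level;
overestimating it loses control.  This asymmetry is the practical argument
for conservative blocking priors.

## The scenario generator

`scenario_spec()` + `simulate_scenario()` generate lattice data with known
ground truth: seeded region growing produces contiguous latent blocks
(size law `"uniform12_14"` for the large-block regime, `"mean4"`, or
`"singleton"`), blocks are shifted between groups with probability
`shift_fraction`, and Gaussian noise is added, independent or spatially
correlated (squared-exponential kernel).  Defaults are chosen once to mimic
a modest imaging comparison: $1$ noise-SD shifts on 20% of blocks, block
base means $\mathcal N(0, 1)$, 30 samples per group.  Growth picks each
next vertex among the frontier positions with the fewest unassigned
neighbours (ties broken at random): filling concave corners first keeps
regions from stranding enclosed pockets.  A region that still runs out of
frontier below the size law's minimum is merged into an adjacent block, so
a small fraction of blocks may exceed the nominal size range — the tests
assert the law holds for the overwhelming majority rather than universally.

What the generator does *not* emulate: registration artifacts, non-Gaussian
intensity distributions, long-range covariance structure of real MRI, and
spatially varying noise levels.  Passing the FDR suite on these scenarios
therefore demonstrates internal consistency of the method under its own
assumptions (and mild violations: non-graph-respecting truth, spatial
noise), not performance on real images.

Two permutation experiments probe the method from opposite directions.
Permuting *sample labels* destroys all group signal while keeping spatial
structure: essentially no discoveries should survive.  Permuting *voxels*
keeps every vertex's own signal but destroys spatial coherence: detections
should thin out markedly, because the model can no longer borrow strength
from neighbours.  Note the second experiment changes the whole shape of the
$l_v$ distribution, not just its lower tail — confident nulls also lose
their neighbourhood support and drift toward $p_0$ — so "dampening" is
asserted on the detection rate (the count of small $l_v$), which is the
quantity of scientific interest.

## Numerical choices and degenerate inputs

* All mixture arithmetic is in log space with log-sum-exp; configuration
  weights routinely span hundreds of log units.
* If $A + (M_X - 1)S_1$ is not positive definite it is nudged by
  $\varepsilon I$ with $\varepsilon = 10^{-8}\,\mathrm{tr}/N$ (with a
  warning); a still-singular matrix is an error advising a larger prior
  scale.
* Newton iterations are damped by step halving with an Armijo condition and
  ridge-repaired if the Hessian is not negative definite; the reference path
  retries from a prior-centred start before giving up.
* $p_0 \in \{0, 1\}$ is handled as an exact limit (configurations with
  $-\infty$ prior mass are skipped; $p_0 = 1$ forces $l_v = 1$).  Because a
  noisy Storey estimate can clip at exactly 1 on mostly-null data — which
  would shut the mixture off — `estimate_hyperparams()` caps the plug-in
  value at 0.999; `estimate_p0()` itself is left exact.
* Ties in rank-based scores use midranks; zero-variance vertices get
  p-value 1 (with a warning) in the Welch baseline and are flagged by the
  variance filter.
* Enumeration is capped (default 12 vertices) because the partition count
  grows super-exponentially; the cap is an argument, not a constant.

## Test and simulation sizes

The automated checks run at deliberately modest sizes: the FDR-control suite
uses a 20&times;25 lattice with 30 samples per group and three replicates;
the toy-system checks use $10^4$ pairs ($10^5$ for the mis-specification
experiment); oracle comparisons use 2- and 3-vertex graphs where quadrature
is exact.  These sizes give Monte-Carlo error small enough for the stated
tolerances while keeping the whole suite inside a coffee break; the model
itself has no dependence on them.

## Known limitations

* The local-window strategy suppresses any direct influence of data beyond
  the window; power gains are limited to spatial scales near the window
  size.
* Calibration of very small $l_v$ at block boundaries is imperfect: a null
  vertex whose window is dominated by shifted neighbours can receive an
  overconfident score.  Averaged over a lattice the controlled-FDR bound
  still holds in our experiments, but single-vertex posterior probabilities
  near zero should not be over-interpreted.
* Hyperparameter estimation is moment-based and global; strong spatial
  nonstationarity would call for slice-wise or regional estimates (the
  functions accept any user-supplied `hyperparams()`).
* Enumeration limits neighbourhoods to roughly a dozen vertices; larger
  windows would require sampling partitions rather than enumerating them,
  which is out of scope here.
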