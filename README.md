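# graphlfdr

Local false discovery rates for two-group comparisons of graph-associated
measurements — voxel-wise brain-image testing being the motivating case.
Mass-univariate pipelines test each vertex on its own and correct afterwards;
when true effects are weak but form connected patches on the graph, that
throws away the most useful structure in the data.  `graphlfdr` scores each
vertex with an empirical-Bayes mixture model that borrows strength from its
graph neighbourhood, gaining power exactly when non-null vertices cluster.

## The model

For a small subgraph around the vertex on test, group means are constrained
to be constant on the blocks of a *graph-respecting partition* Ψ (every
block induces a connected subgraph), and each block k carries an indicator
Δ<sub>k</sub> of whether its mean shifts between the groups.  The local FDR
of vertex v is the posterior probability that its block is unshifted:

> l<sub>v</sub> = P(H<sub>0,v</sub> | X, Y) = Σ<sub>Ψ,Δ</sub> (1 −
> Δ<sub>k(v)</sub>) 1[v ∈ b<sub>k</sub>] P(Δ, Ψ | X, Y)

with a uniform prior over the (exhaustively enumerated) graph-respecting
partitions and i.i.d. Bernoulli block states (null with probability
p<sub>0</sub>).  Given the discrete state, samples are multivariate Gaussian
with unrestricted covariances under conjugate inverse-Wishart priors — the
likelihood does *not* factor over blocks — which integrate out analytically
to a determinant-ratio form; the remaining free block means are integrated
by Laplace approximation.  Hyperparameters (μ<sub>0</sub>, τ², δ<sub>0</sub>,
σ², df, scale matrices A and B, p<sub>0</sub>) are estimated once from the
whole lattice.  The mean of l<sub>v</sub> over a reported list (the
*controlled FDR*) bounds the list's expected false-discovery proportion.

The package also ships the enumeration machinery (1434 graph-respecting
partitions of the 3×3 lattice versus Bell(9) = 21147 unrestricted ones),
a closed-form two-pair toy system exhibiting the blocking phenomenon,
lattice scenario simulators with known ground truth, permutation
experiments, and Welch-t/BH and Storey q-value baselines.

## Worked example

Simulate a 12×12 lattice with contiguous latent blocks, 20% of them shifted
by one noise SD, 30 samples per group, then score every vertex:

```r
library(graphlfdr)

sc  <- scenario_spec(dims = c(12, 12), M_X = 30, M_Y = 30,
                     shift_fraction = 0.2, shift_magnitude = 1, seed = 9)
sim <- simulate_scenario(sc)          # data + ground truth (42/144 non-null)
fit <- graphmm(sim$data, nbhd = "star2d")
summary(fit)
#> graphmm fit on a 12x12 lattice (star2d neighbourhood)
#> local FDR quartiles:
#>     0%    25%    50%    75%   100%
#> 0.0000 0.0003 0.8598 0.9409 0.9630
#> discoveries:
#>  threshold n_discoveries controlled_fdr
#>       0.01            38   5.873318e-05
#>       0.05            42   2.548533e-03
#>       0.10            42   2.548533e-03
```

The fit separates cleanly: 42 vertices score near zero (discovered at
l<sub>v</sub> ≤ 0.05, controlled FDR 0.002) while the rest sit near the
null probability.  Against the known truth:

```r
L <- discoveries(fit, 0.05)
empirical_fdr_tpr(L, sim$truth$null)
#> empirical FDR: 0.024   TPR: 0.976
ttest_bh(sim$data, 0.05)              # the mass-univariate baseline
#> BH discoveries: 37   TPR: 0.833
```

The graph-aware score recovers 41 of the 42 shifted vertices with one
false discovery; vertex-wise Welch tests with BH correction recover 35.

`graphmm()` accepts `nbhd = "lattice3x3"` (the full in-slice window),
`"star2d"`, or `"star3d"`; results export with `write_lfdr_tsv()` /
`write_lfdr_nifti()`, and `inst/cli/graphlfdr` is a thin command-line
wrapper (`run`, `simulate`, `toy`, `partitions`, `permute`).

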