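# stsimeval

Benchmarking toolkit for spatial transcriptomics simulators: quantify how
faithfully a simulated gene x spot count dataset reproduces a real
reference dataset, and make non-spatial count simulators spatially aware.

## What it does

Simulators are indispensable for validating spatial analysis tools, but a
simulator is only as useful as its fidelity to real data. `stsimeval`
measures that fidelity in three layers:

* **Data properties.** 21 metrics produce per-spot, per-gene and
  spatial-level samples from a dataset: library sizes, TMM normalization
  factors, z-scored log2-CPM moments, zero fractions, mean-variance and
  size-zero relationships, pairwise correlations, domain transition
  matrices, neighborhood-enrichment z-scores, graph centrality summaries,
  cell-type interactions, Moran's I, cross-type L statistics and
  nearest-neighbor correlations.
* **Distribution comparison.** Each real/simulated sample pair is compared
  by a two-sample kernel density statistic, the integrated squared error

  $$T = \int \left[\hat f_1(x) - \hat f_2(x)\right]^2 dx,$$

  computed in closed form through the Gaussian convolution identity and
  standardized to a z value against a seeded permutation null. Lower z =
  more faithful. Raw z values are min-max transformed per metric and
  rank-averaged into overall scores per method.
* **Downstream agreement.** Spatial clustering (ARI/NMI), cell-type
  deconvolution (per-type-normalized RMSE, Jensen-Shannon divergence),
  spatially variable gene detection (precision/recall) and spatial
  cross-correlation (cosine and Mantel agreement of bivariate Moran's I
  matrices), each comparing the analysis result on simulated data against
  the same analysis on the real data, with pluggable methods and built-in
  baselines. A concordance index summarizes ranking consistency.

The package also provides `adapt_simulator()`, a cluster-then-simulate
wrapper: spots are partitioned into spatial clusters and any count
simulator is run independently per cluster, so simulated spots inherit the
real coordinates and the tissue's domain structure survives simulation.
A synthetic-fixture generator (banded lattices with negative-binomial
expression, planted marker genes and Dirichlet cell-type proportions)
supplies ground truth for every test.

## Worked example

```r
library(stsimeval)

# a reference dataset: 16x16 lattice, 4 banded domains, NB expression
cfg  <- synthetic_config(n_spots_side = 16, n_domains = 4, seed = 11)
real <- generate_fixture(cfg)
g    <- build_neighbor_graph(real$coords, k = 6)

# two simulations of it with the same NB simulator:
# per-domain (adaptor) vs whole-matrix
sims <- list(
  adaptor = adapt_simulator(real, builtin_nb_simulator, seed = 1),
  whole   = adapt_simulator(real, builtin_nb_simulator, mode = "whole",
                            seed = 1))

st <- score_table(real, sims, g, seed = 1,
                  metrics = c("libSize", "fracZero", "transitionMatrix"))
st[, c("method", "metric", "raw_z", "transformed")]
#>    method           metric      raw_z transformed
#> 1 adaptor          libSize -0.8102818           0
#> 2 adaptor         fracZero  0.6848710           0
#> 3 adaptor transitionMatrix -0.8891704           0
#> 4   whole          libSize  0.5441667           1
#> 5   whole         fracZero 35.1034935           1
#> 6   whole transitionMatrix 10.2530374           1

overall_rank_score(st, "spot")$overall
#> adaptor   whole
#>       1       2
```

Both modes draw from the same fitted negative-binomial model, so the
adaptor's advantage is purely structural: whole-matrix simulation pools
the domains and flattens their expression differences (visible already in
`fracZero`, z = 35.1 vs 0.7), and once the simulated data are
re-clustered, its domain transition matrix no longer resembles the real
one (z = 10.3 vs -0.9).
The transformed column rescales each metric's z values to [0, 1] across
methods; the overall score is the mean ascending rank of raw z.

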