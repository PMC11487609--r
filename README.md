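# mintnet — metabolic interaction networks from genome-scale models

`mintnet` is an R toolkit for microbial ecologists who want to move beyond
co-occurrence networks: starting from a set of genome-scale metabolic
models (GSMMs, SBML Level 3 + FBC v2, as produced by automated
reconstruction tools), it quantifies *potential metabolic interactions*
between community members and builds and analyzes the resulting
interaction network.

The core quantities, for each ordered model pair (A, B):

- **Seed set** of a model: the minimal set of compounds it cannot
  synthesize endogenously — the source strongly connected components
  (SCCs) of its directed substrate→product metabolite graph, capped at
  `MaxCC` members (default 5); each seed in a component of size *k* has
  confidence *C* = 1/*k*.
- **Competition** MI(A,B) = ΣC(Seed_A ∩ Seed_B) / ΣC(Seed_A) — niche
  overlap, confidence-weighted, in [0,1], asymmetric.
- **Complementarity** MI(A,B) = |Seed_A ∩ ¬Seed_B| / |Seed_A ∩
  (Seed_B ∪ ¬Seed_B)| — the fraction of A's needs that B can itself
  produce, plain cardinalities, in [0,1], asymmetric.
- **Potentially transferable metabolites (PTMs)**: Seed_A ∩ ¬Seed_B,
  i.e. compounds A needs and donor B can make.
- **Metabolic distance**: Euclidean distance between parsimonious-FBA
  flux vectors (FBA maximizing the `Growth` objective, then minimum
  total |flux| at the fixed optimum), raw and per-reaction standardized.
- **Network thresholds**: random-matrix-theory scan (smallest cutoff
  whose eigenvalue nearest-neighbor spacings are consistent with the
  Poisson law e^(−s), by chi-square or Kolmogorov–Smirnov test) or
  standard/modified Z-score outlier detection (cutoff 2.698 or 3.5).
- **Topology**: global properties, degree/betweenness/stress
  centralities, greedy modularity modules, z_i–P_i hub classification
  (z* = 2.5, P* = 0.62), network intersection, bipartite
  microbe–metabolite PTM export, clustered distance heatmaps.

See `vignettes/metabolic-interaction-networks.Rmd` for the methods,
conventions and known limitations.

## Worked example

```r
library(mintnet)

# two toy organisms with complementary chains
A <- make_toy_model(c("a -> b", "b -> c"), model_id = "A")
B <- make_toy_model(c("c -> d", "d -> a"), model_id = "B")
ss <- seed_sets(list(A, B))
ss$A$seeds
#> a
#> 1
mi_competition(ss$A, ss$B)      # no shared seeds
#> [1] 0
mi_complementarity(ss$A, ss$B)  # B produces everything A needs
#> [1] 1
find_ptms(ss)
#>   donor receptor metabolite name
#> 1     A        B          c
#> 2     B        A          a
```

A needs `a` (its only seed, confidence 1) and B can produce it, so `a` is
potentially transferable from donor B to receptor A — and symmetrically
`c` from A to B; competition is 0 because the two seed sets are disjoint.

```r
# parsimonious FBA on a branched toy: direct route vs two-step detour
m <- make_toy_model(
  c("EX_g: g ->", "P1: g -> x", "P2a: g -> y", "P2b: y -> x", "Growth: x ->"),
  bounds = list(EX_g = c(-10, 1000)), objective = "Growth")
p <- pfba(m, "Growth")
p$objective_value   # uptake bound is the only constraint
#> [1] 10
p$total_flux        # pFBA picks the short route: 10+10+10
#> [1] 30

# full pipeline on a simulated 7-organism community
out <- run_pipeline(pipeline_config(
  n_demo_models = 7, seed = 1, out_dir = "demo_out",
  threshold_method = "fixed", threshold = 0.9))
list.files(out)     # seed sets, indices, matrices, distances, network,
                    # centralities, modules, zi-Pi, PTM bipartite, heatmap
```

The same stages are exposed as CLI subcommands
(`exec/mintnet <subcommand> --help`): `simulate-models`, `seedset`,
`phylomint`, `ptm`, `matrix`, `distance`, `threshold-rmt`,
`threshold-zscore`, `build-network`, `net-props`, `modules`,
`merge-attrs`, `intersect`, `ptm-network`, `heatmap`, `run`.

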