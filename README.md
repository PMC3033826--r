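# odnet — organism-degree structure of multi-organism metabolic networks

When the metabolic networks of many organisms are pooled into one *union
network*, each reaction can be tagged with its **organism degree (OD)**: the
number of organisms whose metabolism carries it. `odnet` is an R package for
asking what the spatial arrangement of OD over that network says about
metabolic evolution — whether widely shared reactions sit at the centre,
whether same-OD reactions cluster, how large the connected *metabolic core*
is — and for comparing the answers against a neutral,
biochemistry-constrained model of network growth. It is written for
computational/systems biologists studying comparative metabolism and for
anyone who needs label-correlation statistics on networks with a permutation
null.

## What it computes

Starting from a reaction table (reaction id, substrates, products, organisms;
TSV), the package

1. builds the bipartite metabolite–reaction network, removes **currency
   metabolites** (bipartite connectivity strictly greater than a threshold,
   default 10), and projects onto the directed reaction–reaction network
   (edge `r1 -> r2` iff a product of `r1` is a substrate of `r2`);
2. **coarse-grains** connected same-OD(-bin) reactions into super nodes and
   scores the same-OD clustering against an OD-reshuffling null,
   `Z = (s̄ − μ_rand) / σ_rand`, where `s̄` is the observed mean super-node
   size and `μ_rand`, `σ_rand` summarise the mean super-node size over
   reshuffled replicates (20 by default);
3. measures the **core**: `s_core/N_tot` and `s_core/N_ODmax`, the largest
   top-OD super node relative to the whole network and to all top-OD
   reactions;
4. profiles **mean OD by distance** from the most central reaction (highest
   betweenness among the reactions present in all organisms) and the
   **two-node same-OD correlation** `p_same(k)` — the likelihood that two
   reactions `k` steps apart share an OD — against its reshuffled baseline;
5. simulates the **neutral growth model**: networks accreted reaction by
   reaction on a fixed background universe, constrained only by adjacency,
   with fixed or random seed reactions, size-matched to the organisms, and
   pooled into a model union analysed identically.

Because real multi-organism database snapshots are not shipped, the package
includes a first-class synthetic-data module: `generate_universe()` builds a
connected, near-chain-like reaction universe and `evolve_organisms()` evolves
organism reaction sets along a phylogeny by connected gain and loss, planting
the OD gradient and same-OD clustering that the statistics are designed to
detect. See `vignettes/od-structure-methods.Rmd` for the model, parameter
meanings and limitations.

## Worked example

```r
library(odnet)

universe <- generate_universe(n_reactions = 400, n_metabolites = 500, rng_seed = 1)
dataset  <- evolve_organisms(universe, n_organisms = 30, rng_seed = 2)
net <- project_to_reactions(
  prune_currency_metabolites(as_union_bipartite(dataset), 10))
net
#> reaction network: 310 nodes, 309 directed edges
#>   OD range: 1 - 30

od_species_consistency(net)$fraction   # equal OD => equal species set?
#> [1] 1

supernode_zscore(net, od_bin_width = 1, n_randomizations = 20, rng_seed = 3)
#> mean super-node size 1.6848 vs null 1.1695 +/- 0.0197  (Z = 26.12, 20 reshuffles)

cs <- core_sizes(coarse_grain(net, 1))
unlist(cs[c("s_core", "ratio_total", "ratio_odmax")])
#>      s_core ratio_total ratio_odmax
#> 112.0000000   0.3612903   1.0000000

head(od_vs_distance(net)$per_distance, 4)
#>   distance mean_od  n
#> 1        0      30  1
#> 2        1      30  4
#> 3        2      30  6
#> 4        3      30 11

same_od_correlation(net, max_k = 5, rng_seed = 4)
#> same-OD correlation ( 20 reshuffles )
#>  k    p_same n_pairs null_mean    null_sd
#>  1 0.4077670     309 0.1462783 0.01658830
#>  2 0.3780161     373 0.1458445 0.01808724
#>  3 0.3917051     434 0.1517281 0.02084183
#>  4 0.4121094     512 0.1477539 0.02325929
#>  5 0.4462810     605 0.1452893 0.02347916
```

Reading this: every adjacent same-OD pair carries an identical organism set
(fraction 1), so OD is a faithful compression here. Same-OD reactions cluster
far beyond chance (Z ≈ 26): the mean super-node size 1.68 sits 26 null
standard deviations above the reshuffled expectation 1.17. The 112 reactions
shared by all 30 organisms form a single connected core
(`ratio_odmax = 1`) spanning 36% of the union; mean OD is maximal at the
centre and decays outward; and the probability that two reactions at distance
k ≤ 5 share an OD (≈ 0.38–0.45) is roughly triple its reshuffled baseline
(≈ 0.15).

## The analysis workflow

`analysis/` contains the study as numbered drivers over the package, each a
thin script that prints what it found and writes tables under `results/`:

| script | step |
|---|---|
| `01_simulate_data.R` | generate the universe + 30 tree-evolved organisms |
| `02_build_network.R` | prune, project, OD-tag, consistency check |
| `03_coarse_grain.R` | super nodes, size histogram, z-score, core sizes (ΔOD 1 and 10) |
| `04_structure_profiles.R` | centre, OD-vs-distance profile, same-OD correlation |
| `05_growth_model.R` | fixed- vs random-seed model ensembles and their unions |
| `06_compare_model_vs_data.R` | full pipeline + model-vs-data profile table |

Run them in order from the repository root: `Rscript analysis/01_simulate_data.R`, etc.
The same end-to-end analysis is available programmatically via
`run_analysis(analysis_config(...))`, which writes a deterministic JSON
report.

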