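---
title: "Organism-degree structure of multi-organism metabolic networks: methods"
author: "odnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organism-degree structure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odnet)
```

## The question and the representation

When the metabolic networks of many organisms are pooled into one
*union network*, each reaction can be tagged with its **organism degree
(OD)** — the number of organisms whose metabolism carries it. The OD
compresses a reaction's full phylogenetic profile into a single number, which
makes the evolutionary history of the pooled metabolism accessible to graph
statistics: are widely shared reactions concentrated at the centre of the
network? Do reactions with the same OD sit next to each other? `odnet`
implements that analysis, together with a neutral model of metabolic network
growth used as a reference point for what biochemical adjacency alone can
explain.

A metabolism is represented bipartitely: metabolite and reaction nodes, a
directed link from a metabolite to every reaction consuming it and from a
reaction to every metabolite it produces. Two processing steps precede all
statistics:

1. **Currency-metabolite pruning.** Ubiquitous compounds (water, ATP, NADH,
   protons) connect to so many reactions that they would dominate any
   projection. Every metabolite whose total bipartite connectivity (substrate
   plus product links) exceeds a threshold is removed; the default threshold
   is 10 and the comparison is strict, so a metabolite with connectivity
   exactly 10 survives. Pruning is a plain degree cut and always precedes
   projection.
2. **Reaction projection.** The directed reaction–reaction network has an
   edge `r1 -> r2` whenever some product of `r1` is a substrate of `r2`.
   Self-loops are dropped and parallel edges collapsed: all downstream
   statistics are defined on simple graphs. A reversible reaction must be
   encoded as a single table row in its canonical direction; the package does
   not model reversibility.

All distance-based statistics (betweenness, shells, pair separations,
coarse-graining connectivity, growth-model adjacency) use the **undirected
view** of this projection. The distance profile is defined that way, no
statistic requires direction, and using one convention throughout keeps the
union and model analyses comparable.

## Coarse-graining and the reshuffling null

Reactions that are connected to each other and share one OD bin are collapsed
into a *super node* by a depth-first search restricted to same-bin edges. Bin
boundaries are anchored at 1: with bin width $\Delta$, a node of OD $o$ falls
in bin $\lceil o / \Delta \rceil$ (so width 10 gives bins 1–10, 11–20, ...).
Width 1 — exact OD equality — is the default; widths 10 and 50 are sensible
for unions of a hundred or more organisms, where exact ties become sparse.
Two super nodes are joined iff at least one reaction in each is linked to one
in the other; by construction no two adjacent super nodes share a bin, and
the super-node sizes always sum to the number of reactions.

Whether same-OD reactions cluster more than chance is measured against a
label-permutation null: the OD values are reshuffled uniformly over the nodes
(topology untouched, OD frequencies preserved) and the partition is recomputed
from scratch. With $\bar s$ the observed mean super-node size and
$\mu_\mathrm{rand}, \sigma_\mathrm{rand}$ the mean and standard deviation of
the mean super-node size over the reshuffled replicates,

$$Z = \frac{\bar s - \mu_\mathrm{rand}}{\sigma_\mathrm{rand}}.$$

Twenty replicates are the default; the replicate count and seed are recorded
in the result. A network whose OD values are all equal makes every reshuffle
identical — that degenerate null is reported as an error rather than an
infinite or undefined $Z$. No tail p-value is attached to $Z$: with a handful
of replicates the normal tail is not an estimate worth reporting, and the
z-score itself is the quantity of interest.

The **metabolic core** is the largest super node in the top occupied OD bin.
Its size $s_\mathrm{core}$ is reported twice: relative to all reactions
($s_\mathrm{core}/N_\mathrm{tot}$, how much of the union the core spans) and
relative to all top-bin reactions ($s_\mathrm{core}/N_{OD\max}$, how
clustered the most widely shared reactions are). Both ratios depend on
$\Delta$, so the bin width is part of the report.

## Centre, gradient and two-node correlation

The network centre is the reaction with the highest betweenness centrality
*conditioned on being present in all organisms* (maximum OD). Conditioning
and argmax can disagree on large, heterogeneous unions, so the unconditioned
argmax is logged alongside. Ties — possible on symmetric toy graphs — break
to the lexicographically smallest reaction id, recorded in the output.
Betweenness is computed unnormalized with endpoints excluded.

Two statistics quantify the core–periphery picture:

* `od_vs_distance()`: breadth-first shells from the centre; per shell, the
  arithmetic mean OD. Unreachable nodes are excluded and counted. The global
  mean OD is attached as the natural reference line.
* `same_od_correlation()`: for each separation $k$, the fraction of unordered
  node pairs at shortest-path distance exactly $k$ whose ODs are equal. Each
  unordered pair contributes once; pairs in different components have no
  distance and are excluded; a $k$ with no pairs is omitted rather than
  reported as zero. Equality is exact OD by default (a bin-width option
  exists for large unions). The baseline is the same statistic after OD
  reshuffling, averaged over 20 replicates (mean and SD per $k$). Under a
  uniform permutation the expected baseline is flat in $k$ at
  $\sum_o f_o(f_o-1)/(N(N-1))$ with $f_o$ the OD frequencies — a closed form
  the test suite checks by simulation.

## The neutral growth model

The growth model asks how much of the observed structure follows from
biochemical adjacency alone, with no selection. It runs on a fixed
*background* of possible reactions — the projected, pruned universe,
restricted to its giant weakly connected component so that any seed can in
principle reach any reaction. Starting from a single seed reaction, each step
either **adds** (probability $p$) a reaction chosen uniformly among the
background neighbours of the current set, or **removes** (probability
$1 - p$) a uniformly chosen leaf — a reaction with exactly one link, in plus
out, in the current induced subgraph. Leaf removal cannot disconnect the set;
the seed itself is never removed, which keeps the contract total for $p < 1$
(the pure-growth regime $p = 1$, the default, never removes anything). A run
stops at its target size; an addition step that finds the frontier empty
first raises an explicit stalled-growth error naming the achieved size —
silent truncation would break the size-matching that the ensemble design
requires.

An ensemble draws one run per organism, size-matched to the organism reaction
sets, either from one **fixed** seed (the analogue of seeding from a reaction
present in all organisms) or from a fresh uniformly **random** seed per run.
Per-run RNG streams are derived from the master seed, so single runs can be
reproduced in isolation. The pooled runs form a model union with OD = number
of runs containing the reaction, which is analysed by exactly the same
functions as the organism union. Fixed seeding concentrates the runs around a
shared core and produces a heavier high-OD tail than random seeding — the
diagnostic contrast between the two schemes.

## What the synthetic data emulate — and what they do not

Real inputs for this analysis are curated multi-organism reaction databases;
those snapshots are out of scope here. The generator instead produces data
with the statistical structure the analysis assumes, with known ground truth:

* **Universe** (`generate_universe()`): reactions laid down sequentially,
  each consuming a metabolite produced earlier and producing
  $1 + \mathrm{Poisson}(\lambda)$ fresh metabolites, so the projection is
  weakly connected by construction. `mean_out_degree` (default 1.2) sets the
  mean products per reaction — slightly above one, as in currency-pruned real
  networks. `chain_bias` (default 0.8) is the probability that a new reaction
  extends the most recent chain rather than branching off a uniformly chosen
  earlier product.
* **Organisms** (`evolve_organisms()`): a root genome grown as a connected
  set of `root_genome_size` reactions (default 30% of the universe) around a
  fixed root (the highest-degree reaction), then evolved along a phylogeny
  (random unit-branch-length binary tree by default; a coalescent option and
  user Newick are available). Per branch of length $L$,
  $\mathrm{Poisson}(\mathrm{gain\_rate}\cdot L)$ gains each attach a uniform
  frontier neighbour — gains happen at the periphery, mirroring the growth
  model — and $\mathrm{Poisson}(\mathrm{loss\_rate}\cdot L)$ losses each
  remove a uniform leaf (gains before losses within a branch; the root
  reaction is protected, so every set stays connected and non-empty).
  Defaults of 30 organisms, gain 20 and loss 4 per unit branch were chosen so
  that organism sets overlap substantially but not trivially (set sizes
  roughly 150–300 on a 400-reaction universe), giving both an OD gradient and
  same-OD clustering.

Tree-structured gain/loss is the simplest mechanism that plants the two
regularities the analysis measures, which is exactly why it is used: every
downstream statistic can be checked against a known construction. The
generator does **not** emulate stoichiometry, reversibility, compartments,
horizontal transfer of multi-reaction chunks, annotation error, or database
incompleteness — so green tests certify the statistics and their null models,
not the biology of any particular database snapshot.

One geometric property matters for interpreting the gradient statistics.
`chain_bias` controls the effective dimensionality of the universe: near 1
the universe is quasi-linear, and a connected core of $s$ reactions is an
*interval* spanning about $s$ distance steps, so shell-mean OD is high at
both ends of the core and the profile is U-shaped rather than monotone.
Gradient-recovery experiments (and the corresponding tests) therefore use a
branching universe (`chain_bias = 0.3`), where a ball of the same size is
compact and distance from the centre genuinely indexes evolutionary recency.
The default remains 0.8, which is the right regime for the clustering and
consistency statistics.

## Numerical and design choices

* **Determinism.** Every stochastic entry point takes an integer seed and
  restores the caller's RNG state. `derive_seeds()` fans a master seed into
  named per-stage (or per-run) streams, so `run_analysis()` writes
  byte-identical JSON reports for identical config + seed, while any stage
  can be re-run alone.
* **Canonical containers.** Networks store sorted node sets and link tables,
  so structural equality is `identical()` and serialisations are stable.
* **Ties.** Central-node ties break lexicographically; the root reaction of
  the generator (maximum projected degree) breaks ties the same way.
* **Degenerate inputs.** Empty networks coarse-grain to empty partitions;
  constant-OD networks give a degenerate-null error for the z-score; isolated
  or unreachable nodes are counted, not silently dropped; a `k` or distance
  shell with no members is omitted.
* **Problem sizes.** The shipped workflow and tests use universes of a few
  hundred reactions and 30 organisms — large enough that every statistic is
  in its asymptotic regime (z-scores of order 25–30, correlation curves well
  separated from their baselines) and small enough to keep the whole analysis
  in seconds. All sizes are parameters; nothing in the implementation is
  specific to these scales except the quadratic distance matrix in
  `same_od_correlation()`, which is comfortable to a few thousand nodes.

## Known limitations

* The analysis treats the union network as a simple graph; multi-edges from
  repeated metabolite sharing carry no extra weight.
* OD discards which organisms carry a reaction; the consistency check
  (`od_species_consistency()`) quantifies how much that loses on a given
  dataset, but the package offers no profile-level statistics beyond it.
* The growth model is deliberately minimal: no substrate-availability check
  before an addition, no chunk-wise gain/loss, and $p < 1$ is supported but
  not the default workflow regime.
* The synthetic generator's phylogenies are random binary trees with unit
  branch lengths by default; calibrating the generator to any real database's
  summary statistics is out of scope.
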