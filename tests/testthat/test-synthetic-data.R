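test_that("generated universes are connected, chain-like and deterministic", {
  u1 <- generate_universe(500, 600, mean_out_degree = 1.2, rng_seed = 1)
  u2 <- generate_universe(500, 600, mean_out_degree = 1.2, rng_seed = 1)
  expect_identical(u1, u2)

  # giant weakly connected component, checked by an independent BFS sweep
  proj <- project_to_reactions(u1)
  sizes <- component_sizes_bfs(proj)
  expect_gte(max(sizes) / length(proj$nodes), 0.9)

  # empirical mean out-degree (products per reaction) within 20% of target
  out_deg <- nrow(u1$product_links) / length(u1$reactions)
  expect_lt(abs(out_deg - 1.2) / 1.2, 0.2)

  # a different seed gives a different universe
  expect_false(identical(u1, generate_universe(500, 600, rng_seed = 2)))
})

test_that("the smallest chain projects to a single directed edge", {
  u <- chain_universe(2)
  proj <- project_to_reactions(u)
  expect_identical(proj$edges, data.frame(from = "r01", to = "r02"))
})

test_that("infeasible universe parameters are rejected", {
  expect_error(generate_universe(10, 5), "infeasible")
  expect_error(generate_universe(1, 10))
  expect_error(generate_universe(10, 20, mean_out_degree = 0))
})

test_that("random phylogenies are binary with the requested leaves", {
  nw <- generate_phylogeny(2, rng_seed = 1)
  tr <- ape::read.tree(text = nw)
  expect_equal(ape::Ntip(tr), 2L)

  tr7 <- ape::read.tree(text = generate_phylogeny(7, rng_seed = 3))
  expect_equal(ape::Ntip(tr7), 7L)
  expect_equal(tr7$Nnode, 6L)
  expect_true(all(tr7$edge.length > 0))
  expect_identical(generate_phylogeny(7, rng_seed = 3),
                   generate_phylogeny(7, rng_seed = 3))
})

test_that("user-supplied Newick passes through with default branch lengths", {
  nw <- generate_phylogeny(tree_newick = "((A,B),C);")
  tr <- ape::read.tree(text = nw)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_true(all(tr$edge.length == 1))
  expect_error(generate_phylogeny(tree_newick = "((A,B,C"), "malformed")
})

test_that("zero-rate evolution copies the root genome to every organism", {
  u <- chain_universe(20)
  ds <- evolve_organisms(u, n_organisms = 4, root_genome_size = 8,
                         gain_rate = 0, loss_rate = 0, rng_seed = 1)
  for (s in ds$organism_sets) expect_identical(s, ds$root_genome)
  un <- build_union(ds$organism_sets, project_to_reactions(u))
  expect_true(all(un$od == 4L))
})

test_that("with no losses every organism is a superset of the root genome", {
  u <- generate_universe(120, 150, rng_seed = 5)
  ds <- evolve_organisms(u, n_organisms = 6, root_genome_size = 30,
                         gain_rate = 8, loss_rate = 0, rng_seed = 6)
  for (s in ds$organism_sets) {
    expect_length(setdiff(ds$root_genome, s), 0)
  }
})

test_that("every organism set induces a connected subgraph of the universe", {
  u <- generate_universe(200, 260, rng_seed = 7)
  proj <- project_to_reactions(u)
  ds <- evolve_organisms(u, n_organisms = 8, root_genome_size = 40,
                         gain_rate = 15, loss_rate = 6, rng_seed = 8)
  for (s in ds$organism_sets) {
    sub <- reaction_network(
      s, proj$edges[proj$edges$from %in% s & proj$edges$to %in% s, ])
    expect_identical(component_sizes_bfs(sub), length(s))
  }
})

test_that("datasets are byte-identical under the same seed", {
  u <- generate_universe(100, 130, rng_seed = 2)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(evolve_organisms(u, n_organisms = 5, root_genome_size = 20,
                                 rng_seed = 9), d1)
  write_dataset(evolve_organisms(u, n_organisms = 5, root_genome_size = 20,
                                 rng_seed = 9), d2)
  for (f in c("reactions.tsv", "universe.tsv", "tree.nwk")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("sister organisms are more similar than organisms across the root", {
  u <- chain_universe(40)
  tree <- "((A:1,B:1):1,(C:1,D:1):1);"
  n_rep <- 120
  wins <- 0L
  for (i in seq_len(n_rep)) {
    ds <- evolve_organisms(u, root_genome_size = 10, gain_rate = 5,
                           loss_rate = 2, tree = tree, rng_seed = 10000 + i)
    s <- ds$organism_sets
    sister <- mean(c(jaccard(s$A, s$B), jaccard(s$C, s$D)))
    cross <- mean(c(jaccard(s$A, s$C), jaccard(s$A, s$D),
                    jaccard(s$B, s$C), jaccard(s$B, s$D)))
    if (sister > cross) wins <- wins + 1L
  }
  # one-sided sign test against p = 1/2 (ties count against the signal)
  expect_lt(binom.test(wins, n_rep, alternative = "greater")$p.value, 0.01)
})

test_that("with no losses the mean OD is maximal on the root genome", {
  u <- generate_universe(150, 200, rng_seed = 11)
  ds <- evolve_organisms(u, n_organisms = 10, root_genome_size = 30,
                         gain_rate = 10, loss_rate = 0, rng_seed = 12)
  un <- build_union(ds$organism_sets, project_to_reactions(u))
  in_root <- names(un$od) %in% ds$root_genome
  expect_true(all(un$od[in_root] == 10L))
  expect_gt(mean(un$od[in_root]), mean(un$od[!in_root]))
})

test_that("toy fixtures have their documented structure", {
  ch <- toy_fixture("chain4")
  un <- build_union(ch$organism_sets, project_to_reactions(ch$universe))
  expect_identical(unname(un$od[c("r1", "r2", "r3", "r4")]), c(2L, 2L, 1L, 1L))

  st <- toy_fixture("star")
  us <- build_union(st$organism_sets, project_to_reactions(st$universe))
  expect_identical(unname(us$od[c("hub", "leaf1", "leaf2", "leaf3")]),
                   c(5L, 1L, 2L, 3L))

  tc <- toy_fixture("twocore")
  ut <- build_union(tc$organism_sets, project_to_reactions(tc$universe))
  sg <- coarse_grain(ut, 1)
  expect_setequal(sg$supernodes$size, c(3L, 1L, 3L))
  expect_equal(nrow(sg$edges), 2L)

  expect_error(toy_fixture("nope"), "unknown fixture")
})

test_that("datasets round-trip through the reaction-table dialect", {
  u <- generate_universe(80, 100, rng_seed = 3)
  ds <- evolve_organisms(u, n_organisms = 4, root_genome_size = 15,
                         rng_seed = 4)
  dir <- tempfile()
  write_dataset(ds, dir)
  bp <- read_reaction_table(file.path(dir, "reactions.tsv"))
  expect_identical(bp, as_union_bipartite(ds))
  uni <- read_reaction_table(file.path(dir, "universe.tsv"),
                             require_organisms = FALSE)
  expect_identical(uni, u)
})
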