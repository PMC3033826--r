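write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tsubstrates\tproducts\torganisms", lines), path)
  path
}

test_that("reaction tables are parsed row by row with validation", {
  bp <- read_reaction_table(write_tsv_lines("r1\tm1\tm2\torgA;orgB"))
  expect_identical(bp$reactions, "r1")
  expect_setequal(bp$metabolites, c("m1", "m2"))
  expect_identical(bp$membership, list(r1 = c("orgA", "orgB")))

  expect_error(
    read_reaction_table(write_tsv_lines(c("r1\tm1\tm2\ta", "r1\tm2\tm3\ta"))),
    "duplicate reaction id 'r1' at row 2")
  expect_error(
    read_reaction_table(write_tsv_lines(c("r1\tm1\tm2\ta", "r2\tm2\tm3\t"))),
    "empty organism field at row 2")
  bad <- tempfile()
  writeLines(c("reaction_id\tsubstrates\tproducts", "r1\tm1\tm2"), bad)
  expect_error(read_reaction_table(bad), "must have columns")
})

test_that("a 500-reaction universe survives a write/read round trip", {
  u <- generate_universe(500, 620, rng_seed = 21)
  path <- tempfile(fileext = ".tsv")
  write_reaction_table(u, path)
  expect_identical(read_reaction_table(path, require_organisms = FALSE), u)
})

test_that("currency-metabolite pruning is strict, pure and monotone", {
  # one metabolite wired to 12 reactions, another to exactly 10
  rids <- sprintf("r%02d", 1:12)
  bp <- bipartite_network(
    metabolites = c("atp", "glc", "x"),
    reactions = rids,
    substrate_links = data.frame(metabolite = c(rep("atp", 6), rep("glc", 5)),
                                 reaction = c(rids[1:6], rids[1:5])),
    product_links = data.frame(reaction = c(rids[7:12], rids[6:10], "r11"),
                               metabolite = c(rep("atp", 6), rep("glc", 5), "x")))
  before <- bp
  pruned <- prune_currency_metabolites(bp, threshold = 10)
  expect_false("atp" %in% pruned$metabolites)     # degree 12 > 10: removed
  expect_true("glc" %in% pruned$metabolites)      # degree exactly 10: retained
  expect_identical(pruned$reactions, bp$reactions) # reactions never removed
  expect_identical(bp, before)                     # input untouched

  u <- generate_universe(500, 620, mean_out_degree = 1.6, chain_bias = 0.3,
                         rng_seed = 22)
  removed_at <- function(th) {
    setdiff(u$metabolites, prune_currency_metabolites(u, th)$metabolites)
  }
  expect_true(all(removed_at(20) %in% removed_at(5)))
  # more aggressive pruning can only lose projection edges
  expect_lte(nrow(project_to_reactions(prune_currency_metabolites(u, 5))$edges),
             nrow(project_to_reactions(prune_currency_metabolites(u, 20))$edges))
})

test_that("projection links producer to consumer and drops self-loops", {
  bp <- bipartite_network(
    metabolites = c("m", "q"), reactions = c("r1", "r2"),
    substrate_links = data.frame(metabolite = c("m", "q"),
                                 reaction = c("r2", "r1")),
    product_links = data.frame(reaction = c("r1", "r1"),
                               metabolite = c("m", "q")))
  # r1 produces m consumed by r2; r1 also produces q which r1 itself consumes
  proj <- project_to_reactions(bp)
  expect_identical(proj$edges, data.frame(from = "r1", to = "r2"))
})

test_that("projection matches the incidence-matrix oracle on random networks", {
  set.seed(31)
  for (i in 1:60) {
    bp <- random_bipartite(sample(5:200, 1), sample(5:220, 1))
    expect_identical(project_to_reactions(bp)$edges,
                     oracle_projection_edges(bp))
  }
})

test_that("union networks count organisms and restrict universe edges", {
  u <- chain_universe(3)
  proj <- project_to_reactions(u)
  un <- build_union(list(A = c("r01", "r02"), B = c("r02", "r03")), proj)
  expect_identical(unname(un$od[c("r01", "r02", "r03")]), c(1L, 2L, 1L))

  single <- build_union(list(A = c("r01", "r02")), proj)
  expect_true(all(single$od == 1L))
  # union of one organism is its own induced subgraph
  expect_identical(single$edges, data.frame(from = "r01", to = "r02"))
  expect_identical(single$nodes, c("r01", "r02"))

  expect_error(build_union(list(A = "r99"), proj), "not in universe")
})

test_that("OD bookkeeping: total OD equals total organism set size", {
  u <- generate_universe(150, 180, rng_seed = 41)
  ds <- evolve_organisms(u, n_organisms = 7, root_genome_size = 30,
                         rng_seed = 42)
  un <- build_union(ds$organism_sets, project_to_reactions(u))
  expect_identical(sum(un$od), sum(lengths(ds$organism_sets)))
})

test_that("OD/species-set consistency separates concordant from discordant", {
  # r1 and r3 are adjacent with equal OD = 1 but different organisms
  un <- reaction_network(
    c("r1", "r2", "r3"),
    data.frame(from = c("r1", "r1", "r2"), to = c("r2", "r3", "r3")),
    membership = list(r1 = "A", r2 = c("A", "B"), r3 = "B"))
  res <- od_species_consistency(un)
  expect_equal(res$fraction, 0)
  expect_identical(res$discordant[, c("a", "b")],
                   data.frame(a = "r1", b = "r3"))

  # all organisms identical: every same-OD pair concordant
  ds <- toy_fixture("chain4")
  un2 <- build_union(list(A = ds$organism_sets$B, B = ds$organism_sets$B),
                     project_to_reactions(ds$universe))
  expect_equal(od_species_consistency(un2)$fraction, 1)
})

test_that("consistency fraction equals a brute-force pairwise recount", {
  u <- generate_universe(200, 240, rng_seed = 11)
  ds <- evolve_organisms(u, n_organisms = 6, root_genome_size = 40,
                         rng_seed = 11)
  un <- build_union(ds$organism_sets, project_to_reactions(u))
  res <- od_species_consistency(un)

  # recount: loop over every unordered node pair, test adjacency directly
  adj_key <- unique(paste(pmin(un$edges$from, un$edges$to),
                          pmax(un$edges$from, un$edges$to)))
  n_same <- 0L; n_conc <- 0L
  ns <- un$nodes
  for (i in seq_along(ns)[-length(ns)]) for (j in (i + 1L):length(ns)) {
    a <- ns[i]; b <- ns[j]
    if (!(paste(min(a, b), max(a, b)) %in% adj_key)) next
    if (un$od[a] != un$od[b]) next
    n_same <- n_same + 1L
    if (setequal(un$membership[[a]], un$membership[[b]])) n_conc <- n_conc + 1L
  }
  expect_identical(res$n_pairs, n_same)
  expect_equal(res$fraction, n_conc / n_same)
})

test_that("graphml and edge-list exports carry the OD annotation", {
  ds <- toy_fixture("chain4")
  un <- build_union(ds$organism_sets, project_to_reactions(ds$universe))
  gpath <- tempfile(fileext = ".graphml")
  write_reaction_graphml(un, gpath)
  g <- igraph::read_graph(gpath, format = "graphml")
  got <- setNames(as.integer(igraph::V(g)$od), igraph::V(g)$name)
  expect_identical(got[names(un$od)], un$od)
  epath <- tempfile(fileext = ".tsv")
  write_edge_list(un, epath)
  expect_identical(read.delim(epath, colClasses = "character"), un$edges)
})
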