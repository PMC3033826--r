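path3 <- function() {
  reaction_network(c("a", "b", "c"),
                   data.frame(from = c("a", "b"), to = c("b", "c")),
                   od = c(a = 1L, b = 1L, c = 1L))
}

test_that("betweenness peaks on the middle of a path and is flat on K4", {
  b <- node_betweenness(path3())
  expect_identical(names(which.max(b)), "b")
  expect_equal(unname(b[c("a", "c")]), c(0, 0))

  ids <- c("w", "x", "y", "z")
  k4 <- reaction_network(
    ids, do.call(rbind, lapply(1:3, function(i) {
      data.frame(from = ids[i], to = ids[(i + 1):4])
    })), od = setNames(rep(1L, 4), ids))
  expect_true(all(node_betweenness(k4) == node_betweenness(k4)[1L]))
})

test_that("betweenness matches brute-force path counting on random graphs", {
  set.seed(61)
  for (i in 1:8) {
    net <- random_od_graph(sample(20:60, 1))
    expect_equal(node_betweenness(net), oracle_betweenness(net),
                 tolerance = 1e-10)
  }
})

test_that("the central node is the max-OD betweenness argmax with id ties", {
  ds <- toy_fixture("star")
  un <- build_union(ds$organism_sets, project_to_reactions(ds$universe))
  expect_identical(unclass(central_node(un))[[1L]], "hub")

  # two structurally equivalent max-OD candidates: lexicographic tie-break
  ids <- c("rA", "rB", "mid")
  net <- reaction_network(
    ids, data.frame(from = c("rA", "mid"), to = c("mid", "rB")),
    od = c(rA = 3L, rB = 3L, mid = 1L))
  expect_identical(unclass(central_node(net))[[1L]], "rA")

  # synthetic union: exhaustive argmax over the conditioned set
  u <- generate_universe(150, 180, rng_seed = 13)
  dsn <- evolve_organisms(u, n_organisms = 6, root_genome_size = 30,
                          rng_seed = 13)
  unn <- build_union(dsn$organism_sets, project_to_reactions(u))
  btw <- node_betweenness(unn)
  cand <- names(unn$od)[unn$od == max(unn$od)]
  best <- sort(cand[btw[cand] == max(btw[cand])])[1L]
  expect_identical(unclass(central_node(unn))[[1L]], best)
  # the unconditioned argmax is logged alongside
  allbest <- sort(names(btw)[btw == max(btw)])[1L]
  expect_identical(attr(central_node(unn), "unconditioned"), allbest)
})

test_that("OD shells from the star hub average as hand-computed", {
  ds <- toy_fixture("star")
  un <- build_union(ds$organism_sets, project_to_reactions(ds$universe))
  prof <- od_vs_distance(un, "hub")
  expect_identical(prof$per_distance$distance, c(0L, 1L))
  expect_equal(prof$per_distance$mean_od, c(5, 2))  # (1 + 2 + 3) / 3 = 2
  expect_equal(prof$per_distance$n, c(1L, 3L))
  expect_equal(prof$global_mean_od, mean(c(5, 1, 2, 3)))
  expect_equal(prof$unreachable_count, 0L)

  single <- reaction_network("r", data.frame(from = character(0),
                                             to = character(0)),
                             od = c(r = 4L))
  p1 <- od_vs_distance(single, "r")
  expect_identical(p1$per_distance,
                   data.frame(distance = 0L, mean_od = 4, n = 1L))
})

test_that("shell means equal a per-node BFS recount on synthetic unions", {
  u <- generate_universe(150, 180, rng_seed = 2)
  dsn <- evolve_organisms(u, n_organisms = 8, root_genome_size = 30,
                          rng_seed = 2)
  un <- build_union(dsn$organism_sets, project_to_reactions(u))
  ctr <- central_node(un)
  prof <- od_vs_distance(un, ctr)

  # recount: BFS by hand over the undirected adjacency
  nodes <- un$nodes
  adj <- lapply(seq_along(nodes), function(i) character(0))
  names(adj) <- nodes
  for (k in seq_len(nrow(un$edges))) {
    f <- un$edges$from[k]; t <- un$edges$to[k]
    adj[[f]] <- union(adj[[f]], t)
    adj[[t]] <- union(adj[[t]], f)
  }
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[ctr] <- 0
  queue <- unclass(ctr)[[1L]]
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  for (row in seq_len(nrow(prof$per_distance))) {
    d <- prof$per_distance$distance[row]
    shell <- names(dist)[dist == d]
    expect_equal(prof$per_distance$mean_od[row], mean(un$od[shell]))
    expect_identical(prof$per_distance$n[row], length(shell))
  }
  expect_identical(prof$unreachable_count, sum(is.infinite(dist)))
})

test_that("same-OD correlation on a 4-chain matches the 6-pair enumeration", {
  ids <- c("r1", "r2", "r3", "r4")
  net <- reaction_network(
    ids, data.frame(from = ids[1:3], to = ids[2:4]),
    od = setNames(c(1L, 1L, 2L, 2L), ids))
  prof <- same_od_correlation(net, max_k = 3, n_randomizations = 5,
                              rng_seed = 1)
  expect_identical(prof$per_k$k, 1:3)
  expect_equal(prof$per_k$p_same, c(2 / 3, 0, 0))
  expect_identical(prof$per_k$n_pairs, c(3L, 2L, 1L))
})

test_that("identical ODs give p_same = 1 at every separation", {
  net <- reaction_network(
    c("a", "b", "c"), data.frame(from = c("a", "b"), to = c("b", "c")),
    od = c(a = 7L, b = 7L, c = 7L))
  prof <- same_od_correlation(net, max_k = 2, n_randomizations = 2,
                              rng_seed = 1)
  expect_true(all(prof$per_k$p_same == 1))
})

test_that("separations with no pairs are omitted, not reported as zero", {
  prof <- same_od_correlation(path3(), max_k = 10, n_randomizations = 2,
                              rng_seed = 1)
  expect_identical(prof$per_k$k, 1:2)  # a 3-path has no pairs beyond k = 2
})

test_that("the reshuffled baseline is flat at the closed-form expectation", {
  set.seed(62)
  net <- random_od_graph(120, n_edges = 200, max_od = 5L)
  prof <- same_od_correlation(net, max_k = 6, n_randomizations = 200,
                              rng_seed = 63)
  expected <- oracle_permutation_baseline(net$od)
  ok <- abs(prof$baseline_per_k$mean - expected) <= 3 * prof$baseline_per_k$sd /
    sqrt(prof$n_randomizations) + 1e-12
  # allow one 3-sigma excursion across the k range
  expect_gte(sum(ok), nrow(prof$baseline_per_k) - 1L)
})

test_that("profiles are invariant to node relabelling", {
  set.seed(64)
  net <- random_od_graph(60)
  relabel <- setNames(sprintf("x%03d", sample(60)), net$nodes)
  net2 <- reaction_network(
    unname(relabel[net$nodes]),
    data.frame(from = unname(relabel[net$edges$from]),
               to = unname(relabel[net$edges$to])),
    od = setNames(as.integer(net$od), relabel[names(net$od)]))
  p1 <- same_od_correlation(net, max_k = 4, n_randomizations = 2, rng_seed = 1)
  p2 <- same_od_correlation(net2, max_k = 4, n_randomizations = 2, rng_seed = 1)
  expect_equal(p1$per_k, p2$per_k)
})
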