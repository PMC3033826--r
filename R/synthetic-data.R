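#' Generate a near-chain-like background reaction universe
#'
#' Emulates the statistics of a currency-pruned reaction universe: once
#' ubiquitous metabolites are removed, metabolic pathways are close to linear
#' chains, with mean in- and out-degree only slightly above one. Reactions are
#' laid down sequentially; each new reaction consumes a metabolite produced by
#' an earlier reaction (with probability `chain_bias` the immediately
#' preceding one, extending a chain; otherwise a uniformly chosen earlier
#' product, creating a branch) and produces `1 + Poisson(mean_out_degree - 1)`
#' distinct metabolites, fresh ones while available. By construction the
#' reaction-reaction projection is weakly connected.
#'
#' @param n_reactions number of reactions (>= 2).
#' @param n_metabolites number of available metabolite ids; must be at least
#'   `n_reactions + 1` so every reaction can mint a fresh primary product.
#' @param mean_out_degree target mean number of products per reaction (> 0,
#'   realistically slightly above 1); default 1.2.
#' @param chain_bias propensity to extend linear chains rather than branch,
#'   in `[0, 1]`; default 0.8.
#' @param rng_seed optional integer seed.
#' @return a [bipartite_network()] with `membership = NULL`.
#' @export
generate_universe <- function(n_reactions, n_metabolites,
                              mean_out_degree = 1.2, chain_bias = 0.8,
                              rng_seed = NULL) {
  stopifnot(n_reactions >= 2, n_metabolites >= 2, mean_out_degree > 0,
            chain_bias >= 0, chain_bias <= 1)
  if (n_metabolites < n_reactions + 1) {
    stop("infeasible parameters: need n_metabolites >= n_reactions + 1 ",
         "to realize ", n_reactions, " chained reactions")
  }
  rw <- max(4L, nchar(as.character(n_reactions)))
  mw <- max(4L, nchar(as.character(n_metabolites)))
  rids <- sprintf(paste0("r%0", rw, "d"), seq_len(n_reactions))
  mids <- sprintf(paste0("m%0", mw, "d"), seq_len(n_metabolites))

  with_seed(rng_seed, {
    sub_of <- vector("list", n_reactions)
    prod_of <- vector("list", n_reactions)
    produced <- character(0)      # metabolites already produced by someone
    next_fresh <- 2L              # mids[1] is the primordial substrate
    lambda <- max(mean_out_degree - 1, 0)

    for (i in seq_len(n_reactions)) {
      sub <- if (i == 1L) {
        mids[1L]
      } else if (runif(1) < chain_bias) {
        sample1(prod_of[[i - 1L]])
      } else {
        sample1(produced)
      }
      k <- 1L + rpois(1L, lambda)
      n_fresh <- min(k, n_metabolites - next_fresh + 1L)
      prods <- character(0)
      if (n_fresh > 0L) {
        prods <- mids[next_fresh:(next_fresh + n_fresh - 1L)]
        next_fresh <- next_fresh + n_fresh
      }
      if (length(prods) < k) {
        pool <- setdiff(produced, c(prods, sub))
        extra <- min(k - length(prods), length(pool))
        if (extra > 0L) prods <- c(prods, sample(pool, extra))
      }
      sub_of[[i]] <- sub
      prod_of[[i]] <- prods
      produced <- unique(c(produced, prods))
    }

    used <- unique(c(mids[1L], unlist(sub_of), unlist(prod_of)))
    bipartite_network(
      metabolites = used,
      reactions = rids,
      substrate_links = data.frame(
        metabolite = unlist(sub_of),
        reaction = rep(rids, lengths(sub_of))),
      product_links = data.frame(
        reaction = rep(rids, lengths(prod_of)),
        metabolite = unlist(prod_of))
    )
  })
}

#' Generate or normalise a phylogeny
#'
#' Either draws a random rooted binary tree with `n_organisms` leaves (leaf
#' labels `O01`, `O02`, ... ; branch lengths all 1 by default, or
#' coalescent-shaped), or passes a user-supplied Newick string through,
#' filling in missing branch lengths with 1.
#'
#' @param n_organisms number of leaves (>= 2); ignored when `tree_newick` is
#'   supplied.
#' @param tree_newick `"random"` (default) or a Newick string.
#' @param branch_lengths `"unit"` (default) or `"coalescent"`, for random
#'   trees only.
#' @param rng_seed optional integer seed.
#' @return a Newick string.
#' @export
generate_phylogeny <- function(n_organisms = NULL, tree_newick = "random",
                               branch_lengths = c("unit", "coalescent"),
                               rng_seed = NULL) {
  branch_lengths <- match.arg(branch_lengths)
  if (!identical(tree_newick, "random")) {
    tr <- tryCatch(suppressWarnings(ape::read.tree(text = tree_newick)),
                   error = function(e) NULL)
    if (is.null(tr) || is.null(tr$tip.label)) {
      stop("malformed Newick string: ", tree_newick)
    }
    if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
    tr$edge.length[is.na(tr$edge.length)] <- 1
    return(ape::write.tree(tr))
  }
  stopifnot(!is.null(n_organisms), n_organisms >= 2)
  with_seed(rng_seed, {
    tr <- if (branch_lengths == "coalescent") {
      ape::rcoal(n_organisms)
    } else {
      t0 <- ape::rtree(n_organisms)
      t0$edge.length <- rep(1, nrow(t0$edge))
      t0
    }
    tr$tip.label <- sprintf("O%02d", seq_len(n_organisms))
    ape::write.tree(tr)
  })
}

#' Evolve organism reaction sets along a phylogeny
#'
#' The generative model behind the synthetic datasets: a root genome is grown
#' as a connected set around a fixed root reaction (the highest-degree node of
#' the projected universe, ties broken lexicographically), then evolved down
#' the tree. Along each branch of length L, `Poisson(gain_rate * L)` gains
#' each add a uniformly chosen frontier neighbour (a universe reaction
#' adjacent to the current set — gains attach at the periphery), and
#' `Poisson(loss_rate * L)` losses each remove a uniformly chosen leaf of the
#' induced subgraph (never the root reaction, so sets stay connected and
#' non-empty). Gains are applied before losses on each branch. Tree-correlated
#' gain/loss plants exactly the structure the analysis measures: OD decays
#' with distance from the shared core, and same-OD reactions cluster.
#'
#' @param universe a [generate_universe()] result (or any organism-free
#'   [bipartite_network()]).
#' @param n_organisms number of organisms when a random tree is drawn;
#'   default 30.
#' @param root_genome_size size of the ancestral reaction set; default 30% of
#'   the universe.
#' @param gain_rate expected gains per unit branch length; default 20.
#' @param loss_rate expected losses per unit branch length; default 4.
#' @param tree `"random"` or a Newick string whose tips name the organisms.
#' @param rng_seed optional integer seed; all randomness (tree, root genome,
#'   gain/loss) flows through this one seed.
#' @return an object of class `synthetic_dataset`: `universe`,
#'   `organism_sets` (named list of reaction id vectors), `tree` (Newick),
#'   `root_reaction`, `root_genome`, and `gain_noops` (count of gains
#'   requested while the frontier was empty).
#' @export
evolve_organisms <- function(universe, n_organisms = 30L,
                             root_genome_size = NULL, gain_rate = 20,
                             loss_rate = 4, tree = "random", rng_seed = NULL) {
  stopifnot(inherits(universe, "bipartite_network"),
            gain_rate >= 0, loss_rate >= 0)
  proj <- project_to_reactions(universe)
  n_univ <- length(proj$nodes)
  if (is.null(root_genome_size)) root_genome_size <- ceiling(0.3 * n_univ)
  stopifnot(root_genome_size >= 1, root_genome_size <= n_univ)

  adj <- rn_adjacency(proj)
  deg <- lengths(adj)
  root_idx <- which(deg == max(deg))[1L]  # nodes are sorted: first = smallest id

  with_seed(rng_seed, {
    tr <- if (identical(tree, "random")) {
      stopifnot(n_organisms >= 2)
      t0 <- ape::rtree(n_organisms)
      t0$edge.length <- rep(1, nrow(t0$edge))
      t0$tip.label <- sprintf("O%02d", seq_len(n_organisms))
      t0
    } else {
      ape::read.tree(text = tree)
    }
    if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))

    # ancestral genome: connected growth around the root reaction
    st <- gs_init(adj, root_idx)
    while (st$size < root_genome_size) {
      fr <- gs_frontier(st)
      if (length(fr) == 0L) {
        stop("root genome of size ", root_genome_size,
             " not reachable by connected growth (stalled at ", st$size, ")")
      }
      st <- gs_add(st, sample1(fr))
    }
    root_state <- st
    gain_noops <- 0L

    # preorder edge walk: parents come before children in cladewise order
    tr <- stats::reorder(tr, "cladewise")
    n_tips <- length(tr$tip.label)
    states <- vector("list", n_tips + tr$Nnode)
    states[[n_tips + 1L]] <- root_state
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1L]
      child <- tr$edge[e, 2L]
      len <- tr$edge.length[e]
      st <- states[[parent]]
      for (g in seq_len(rpois(1L, gain_rate * len))) {
        fr <- gs_frontier(st)
        if (length(fr) == 0L) gain_noops <- gain_noops + 1L
        else st <- gs_add(st, sample1(fr))
      }
      for (l in seq_len(rpois(1L, loss_rate * len))) {
        lv <- gs_leaves(st, protect = root_idx)
        if (length(lv) > 0L) st <- gs_remove(st, sample1(lv))
      }
      states[[child]] <- st
    }

    organism_sets <- lapply(seq_len(n_tips), function(i) {
      sort(proj$nodes[states[[i]]$in_set])
    })
    names(organism_sets) <- tr$tip.label
    organism_sets <- organism_sets[order(names(organism_sets))]

    structure(
      list(universe = universe, organism_sets = organism_sets,
           tree = ape::write.tree(tr),
           root_reaction = proj$nodes[root_idx],
           root_genome = sort(proj$nodes[root_state$in_set]),
           gain_noops = gain_noops),
      class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic dataset:", length(x$organism_sets), "organisms on a",
      length(x$universe$reactions), "reaction universe\n")
  cat("  organism set sizes:",
      paste(range(lengths(x$organism_sets)), collapse = " - "), "\n")
  invisible(x)
}

#' Union bipartite network of a synthetic dataset
#'
#' Restricts the universe to the reactions carried by at least one organism
#' and attaches organism membership, i.e. the reaction table a multi-organism
#' database snapshot would provide.
#'
#' @param dataset a [evolve_organisms()] or [toy_fixture()] result.
#' @return a [bipartite_network()] with membership.
#' @export
as_union_bipartite <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  u <- dataset$universe
  pairs <- data.frame(
    organism = rep(names(dataset$organism_sets),
                   lengths(dataset$organism_sets)),
    reaction = unlist(dataset$organism_sets, use.names = FALSE))
  membership <- lapply(split(pairs$organism, pairs$reaction), unique)
  keep <- names(membership)
  sl <- u$substrate_links[u$substrate_links$reaction %in% keep, ]
  pl <- u$product_links[u$product_links$reaction %in% keep, ]
  bipartite_network(
    metabolites = unique(c(sl$metabolite, pl$metabolite)),
    reactions = keep, substrate_links = sl, product_links = pl,
    membership = membership)
}

#' Write a synthetic dataset to disk
#'
#' Writes `<dir>/reactions.tsv` (the union reaction table with organism
#' membership), `<dir>/universe.tsv` (the full background universe, organisms
#' field empty) and `<dir>/tree.nwk`; all round-trip through
#' [read_reaction_table()].
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reaction_table(as_union_bipartite(dataset),
                       file.path(dir, "reactions.tsv"))
  write_reaction_table(dataset$universe, file.path(dir, "universe.tsv"))
  writeLines(dataset$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}

#' Hand-checkable toy datasets
#'
#' Small hard-coded datasets whose expected outputs at every downstream stage
#' are documented here:
#'
#' * `"chain4"`: a 4-reaction chain `r1 -> r2 -> r3 -> r4`; organisms
#'   `A = {r1, r2}`, `B = {r1, r2, r3, r4}`, so the union ODs along the chain
#'   are 2, 2, 1, 1 and coarse-graining at bin width 1 gives two super nodes
#'   of sizes 2 and 2 joined by one super edge.
#' * `"star"`: a hub producing three metabolites consumed by three leaf
#'   reactions; five organisms all carry the hub (OD 5) and the leaves have
#'   ODs 1, 2, 3, so the hub is the central node and the distance profile is
#'   mean OD 5 at d = 0 and 2 at d = 1.
#' * `"twocore"`: a 7-reaction chain `r1 r2 r3 b r4 r5 r6` with ODs
#'   3, 3, 3, 1, 2, 2, 2 — two same-OD clusters of size 3 bridged by one
#'   low-OD reaction, giving three super nodes (sizes 3, 1, 3) at bin width 1.
#'
#' @param name one of `"chain4"`, `"star"`, `"twocore"`.
#' @return a `synthetic_dataset`.
#' @export
toy_fixture <- function(name) {
  chain_universe <- function(rids) {
    # r_i consumes m_{i-1}, produces m_i
    n <- length(rids)
    mids <- sprintf("m%d", 0:n)
    bipartite_network(
      metabolites = mids, reactions = rids,
      substrate_links = data.frame(metabolite = mids[1:n], reaction = rids),
      product_links = data.frame(reaction = rids, metabolite = mids[2:(n + 1)]))
  }
  ds <- switch(
    name,
    chain4 = list(
      universe = chain_universe(c("r1", "r2", "r3", "r4")),
      organism_sets = list(A = c("r1", "r2"), B = c("r1", "r2", "r3", "r4")),
      tree = "(A:1,B:1);",
      root_reaction = "r1", root_genome = c("r1", "r2")),
    star = list(
      universe = bipartite_network(
        metabolites = c("m0", "m1", "m2", "m3"),
        reactions = c("hub", "leaf1", "leaf2", "leaf3"),
        substrate_links = data.frame(
          metabolite = c("m0", "m1", "m2", "m3"),
          reaction = c("hub", "leaf1", "leaf2", "leaf3")),
        product_links = data.frame(
          reaction = "hub", metabolite = c("m1", "m2", "m3"))),
      organism_sets = list(
        o1 = c("hub", "leaf1", "leaf2", "leaf3"),
        o2 = c("hub", "leaf2", "leaf3"),
        o3 = c("hub", "leaf3"),
        o4 = "hub", o5 = "hub"),
      tree = "((o1:1,o2:1):1,(o3:1,(o4:1,o5:1):1):1);",
      root_reaction = "hub", root_genome = "hub"),
    twocore = list(
      universe = chain_universe(c("r1", "r2", "r3", "b", "r4", "r5", "r6")),
      organism_sets = list(
        o1 = c("r1", "r2", "r3", "b", "r4", "r5", "r6"),
        o2 = c("r1", "r2", "r3"),
        o3 = c("r1", "r2", "r3"),
        o4 = c("r4", "r5", "r6")),
      tree = "((o1:1,o4:1):1,(o2:1,o3:1):1);",
      root_reaction = "r2", root_genome = c("r1", "r2", "r3")),
    stop("unknown fixture '", name,
         "'; available: chain4, star, twocore")
  )
  ds$gain_noops <- 0L
  structure(ds, class = "synthetic_dataset")
}
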