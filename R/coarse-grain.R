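#' Coarse-grain a reaction network into same-OD super nodes
#'
#' Collapses every maximal set of reactions that are connected to each other
#' (undirected view) and fall in the same OD bin into one super node, using an
#' explicit depth-first search restricted to same-bin edges. With
#' `od_bin_width = 1` two neighbours merge only when their OD is exactly
#' equal; wider bins (e.g. 10: OD 1..10, 11..20, ...) compensate for the
#' natural sparseness of OD in large unions. Bin boundaries are anchored at 1,
#' so a node's bin index is `ceiling(od / od_bin_width)`. Two super nodes are
#' joined iff at least one reaction in each is linked to one in the other.
#'
#' @param net a [reaction_network()] with OD annotation.
#' @param od_bin_width positive integer bin width (the OD range merged into
#'   one super node); default 1.
#' @return an object of class `supernode_graph`: `supernodes` (data.frame with
#'   `id`, `od_bin`, `size`), `members` (named list of reaction ids), `edges`
#'   (data.frame of unordered super-node id pairs), `od_bin_width`,
#'   `source_n_nodes` (total reactions) and `n_odmax` (reactions in the top
#'   occupied bin).
#' @export
coarse_grain <- function(net, od_bin_width = 1L) {
  stopifnot(inherits(net, "reaction_network"), od_bin_width >= 1)
  od_bin_width <- as.integer(od_bin_width)
  n <- length(net$nodes)
  if (n == 0L) {
    return(structure(
      list(supernodes = data.frame(id = character(0), od_bin = integer(0),
                                   size = integer(0)),
           members = list(),
           edges = data.frame(a = character(0), b = character(0)),
           od_bin_width = od_bin_width, source_n_nodes = 0L, n_odmax = 0L),
      class = "supernode_graph"))
  }
  if (is.null(net$od)) stop("OD annotation required for coarse-graining")
  bin <- as.integer(ceiling(net$od[net$nodes] / od_bin_width))
  adj <- rn_adjacency(net)

  # iterative DFS over same-bin edges
  comp <- integer(n)
  ncomp <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    stack <- start
    comp[start] <- ncomp
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (w in adj[[v]]) {
        if (comp[w] == 0L && bin[w] == bin[v]) {
          comp[w] <- ncomp
          stack <- c(stack, w)
        }
      }
    }
  }

  ids <- sprintf("sn%04d", seq_len(ncomp))
  members <- split(net$nodes, comp)
  names(members) <- ids
  sizes <- lengths(members)
  comp_bin <- bin[match(vapply(members, `[[`, "", 1L), net$nodes)]
  supernodes <- data.frame(id = ids, od_bin = comp_bin, size = as.integer(sizes))

  # super-node edges: any reaction-level link between different super nodes
  se <- data.frame(a = character(0), b = character(0))
  if (nrow(net$edges) > 0L) {
    ca <- comp[match(net$edges$from, net$nodes)]
    cb <- comp[match(net$edges$to, net$nodes)]
    keep <- ca != cb
    if (any(keep)) {
      se <- unique(data.frame(a = ids[pmin(ca[keep], cb[keep])],
                              b = ids[pmax(ca[keep], cb[keep])]))
      se <- se[order(se$a, se$b), , drop = FALSE]
      rownames(se) <- NULL
    }
  }

  top_bin <- max(supernodes$od_bin)
  structure(
    list(supernodes = supernodes, members = members, edges = se,
         od_bin_width = od_bin_width, source_n_nodes = n,
         n_odmax = sum(sizes[supernodes$od_bin == top_bin])),
    class = "supernode_graph")
}

#' @export
print.supernode_graph <- function(x, ...) {
  cat("super-node graph:", nrow(x$supernodes), "super nodes over",
      x$source_n_nodes, "reactions (bin width", x$od_bin_width, ")\n")
  invisible(x)
}

#' Histogram of super-node sizes
#'
#' @param sg a [coarse_grain()] result.
#' @param cumulative when `TRUE`, returns for each size `s` the number of
#'   super nodes of size at least `s`.
#' @return data.frame with columns `size` and `count`.
#' @export
size_histogram <- function(sg, cumulative = FALSE) {
  stopifnot(inherits(sg, "supernode_graph"))
  sizes <- sg$supernodes$size
  if (length(sizes) == 0L) return(data.frame(size = integer(0), count = integer(0)))
  if (cumulative) {
    s <- seq_len(max(sizes))
    data.frame(size = s,
               count = vapply(s, function(k) sum(sizes >= k), integer(1)))
  } else {
    tb <- table(sizes)
    data.frame(size = as.integer(names(tb)), count = as.integer(tb))
  }
}

#' Reshuffle the OD labels of a network
#'
#' The null model for OD structure: topology is untouched while the OD values
#' are redistributed over the nodes by a uniform random permutation, so each
#' OD value keeps its frequency but loses its placement. Organism membership
#' is dropped, as it is no longer meaningful.
#'
#' @param net a [reaction_network()] with OD.
#' @param rng_seed optional integer seed; `NULL` uses the current RNG stream.
#' @return a [reaction_network()] with permuted OD.
#' @export
reshuffle_od <- function(net, rng_seed = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  if (is.null(net$od)) stop("OD annotation required")
  perm <- with_seed(rng_seed, sample(unname(net$od)))
  reaction_network(net$nodes, net$edges, od = setNames(perm, net$nodes))
}

#' Z-score of the mean super-node size against the reshuffling null
#'
#' Quantifies same-OD clustering: compares the observed mean super-node size
#' `s_bar` against its distribution when the OD labels are randomly
#' reshuffled, as `Z = (s_bar - mu_rand) / sigma_rand`, where `mu_rand` and
#' `sigma_rand` are the mean and standard deviation of the mean super-node
#' size over `n_randomizations` independent reshuffles (each re-partitioned
#' from scratch).
#'
#' @param net a [reaction_network()] with OD.
#' @param od_bin_width OD bin width, as in [coarse_grain()].
#' @param n_randomizations number of reshuffled replicates (>= 2); default 20.
#' @param rng_seed optional integer seed.
#' @return an object of class `supernode_zscore`: `mean_size`, `null_mean`,
#'   `null_sd`, `z`, `null_values`, `n_randomizations`, `rng_seed`.
#' @export
supernode_zscore <- function(net, od_bin_width = 1L, n_randomizations = 20L,
                             rng_seed = NULL) {
  stopifnot(n_randomizations >= 2L)
  s_bar <- mean(coarse_grain(net, od_bin_width)$supernodes$size)
  null_values <- with_seed(rng_seed, vapply(seq_len(n_randomizations), function(i) {
    mean(coarse_grain(reshuffle_od(net), od_bin_width)$supernodes$size)
  }, numeric(1)))
  mu <- mean(null_values)
  sig <- sd(null_values)
  if (sig == 0) {
    stop("degenerate null: every reshuffle gives the same mean super-node size")
  }
  structure(
    list(mean_size = s_bar, null_mean = mu, null_sd = sig,
         z = zscore_from_moments(s_bar, mu, sig), null_values = null_values,
         n_randomizations = as.integer(n_randomizations), rng_seed = rng_seed),
    class = "supernode_zscore")
}

#' Z-score from reported moments
#'
#' `Z = (s_bar - mu_rand) / sigma_rand`, exposed separately so a z-score can
#' be evaluated from summary moments alone.
#'
#' @param s_bar observed mean super-node size.
#' @param mu_rand,sigma_rand null mean and standard deviation.
#' @return the z-score.
#' @export
zscore_from_moments <- function(s_bar, mu_rand, sigma_rand) {
  stopifnot(sigma_rand > 0)
  (s_bar - mu_rand) / sigma_rand
}

#' @export
print.supernode_zscore <- function(x, ...) {
  cat(sprintf("mean super-node size %.4f vs null %.4f +/- %.4f  (Z = %.2f, %d reshuffles)\n",
              x$mean_size, x$null_mean, x$null_sd, x$z, x$n_randomizations))
  invisible(x)
}

#' Size of the metabolic core
#'
#' The core is the largest super node in the top occupied OD bin. Its size
#' `s_core` is reported relative to the total number of reactions (`N_tot`,
#' how much of the network the core spans) and relative to the number of
#' reactions in the top OD bin (`N_ODmax`, how clustered the most widely
#' shared reactions are).
#'
#' @param sg a [coarse_grain()] result (non-empty).
#' @return a list with `s_core`, `n_tot`, `n_odmax`, `ratio_total`
#'   (`s_core / N_tot`), `ratio_odmax` (`s_core / N_ODmax`) and
#'   `od_bin_width`.
#' @export
core_sizes <- function(sg) {
  stopifnot(inherits(sg, "supernode_graph"), nrow(sg$supernodes) > 0L)
  top <- max(sg$supernodes$od_bin)
  s_core <- max(sg$supernodes$size[sg$supernodes$od_bin == top])
  list(s_core = as.integer(s_core),
       n_tot = sg$source_n_nodes,
       n_odmax = sg$n_odmax,
       ratio_total = s_core / sg$source_n_nodes,
       ratio_odmax = s_core / sg$n_odmax,
       od_bin_width = sg$od_bin_width)
}

#' Export a super-node graph
#'
#' GraphML with `size` and `od_bin` node attributes, or a JSON document with
#' the full partition.
#'
#' @param sg a [coarse_grain()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_supernode_graphml <- function(sg, path) {
  g <- igraph::graph_from_data_frame(
    sg$edges, directed = FALSE,
    vertices = data.frame(name = sg$supernodes$id, size = sg$supernodes$size,
                          od_bin = sg$supernodes$od_bin))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_supernode_graphml
#' @export
write_supernode_json <- function(sg, path) {
  jsonlite::write_json(
    list(od_bin_width = sg$od_bin_width, source_n_nodes = sg$source_n_nodes,
         n_odmax = sg$n_odmax, supernodes = sg$supernodes,
         members = sg$members, edges = sg$edges),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
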