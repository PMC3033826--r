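#' Betweenness centrality of reaction nodes
#'
#' Shortest-path betweenness on the undirected view of the reaction network
#' (unnormalized counts, endpoints excluded). Used to locate the centre of the
#' metabolism: high betweenness approximates high mass transfer through a
#' reaction.
#'
#' @param net a [reaction_network()].
#' @return named numeric vector over `net$nodes`.
#' @export
node_betweenness <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  g <- rn_igraph(net, directed = FALSE)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  setNames(as.numeric(b[net$nodes]), net$nodes)
}

#' The most central reaction node
#'
#' Among the reactions of maximum OD (present in the largest number of
#' organisms), returns the one with the highest betweenness centrality; ties
#' are broken by lexicographically smallest id. The unconditioned betweenness
#' argmax over all nodes is attached as attribute `"unconditioned"` for
#' comparison, since the two need not coincide on large unions.
#'
#' @param net a [reaction_network()] with OD annotation.
#' @return a reaction id (character scalar) with attribute `unconditioned`.
#' @export
central_node <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  if (length(net$nodes) == 0L) stop("empty network has no central node")
  if (is.null(net$od)) stop("OD annotation required")
  btw <- node_betweenness(net)
  pick <- function(ids) {
    best <- ids[btw[ids] == max(btw[ids])]
    sort(best)[1L]
  }
  candidates <- net$nodes[net$od == max(net$od)]
  structure(pick(candidates), unconditioned = pick(net$nodes))
}

#' Average OD as a function of distance from the centre
#'
#' Breadth-first shells from `center` on the undirected view; for each
#' distance `d` the arithmetic mean OD of the reactions exactly `d` steps
#' away. A decreasing profile means widely shared reactions sit at the core
#' and organism-specific ones at the periphery. Nodes unreachable from the
#' centre are excluded and counted.
#'
#' @param net a [reaction_network()] with OD.
#' @param center reaction id to measure from; defaults to [central_node()].
#' @return an object of class `od_distance_profile`: `center`, `per_distance`
#'   (data.frame `distance`, `mean_od`, `n`), `global_mean_od` (mean OD over
#'   all nodes, the horizontal reference line) and `unreachable_count`.
#' @export
od_vs_distance <- function(net, center = central_node(net)) {
  stopifnot(inherits(net, "reaction_network"))
  if (is.null(net$od)) stop("OD annotation required")
  center <- as.character(center)
  if (!center %in% net$nodes) stop("center must be a node of the network")
  g <- rn_igraph(net, directed = FALSE)
  d <- igraph::distances(g, v = center, mode = "all")[1L, net$nodes]
  reach <- is.finite(d)
  per <- aggregate(list(mean_od = as.numeric(net$od[net$nodes][reach])),
                   by = list(distance = as.integer(d[reach])), FUN = mean)
  per$n <- as.integer(table(as.integer(d[reach]))[as.character(per$distance)])
  per <- per[order(per$distance), c("distance", "mean_od", "n")]
  rownames(per) <- NULL
  structure(
    list(center = unclass(center)[[1L]], per_distance = per,
         global_mean_od = mean(as.numeric(net$od)),
         unreachable_count = sum(!reach)),
    class = "od_distance_profile")
}

#' @export
print.od_distance_profile <- function(x, ...) {
  cat("OD-vs-distance profile from", x$center, "(global mean OD",
      sprintf("%.2f", x$global_mean_od), ")\n")
  print(x$per_distance, row.names = FALSE)
  invisible(x)
}

#' Two-node same-OD correlation function
#'
#' For each separation `k`, the likelihood that two reactions exactly `k`
#' steps apart (undirected shortest-path distance) have the same OD, over all
#' unordered node pairs; pairs in different components have no distance and
#' are excluded. The baseline is the same statistic after [reshuffle_od()],
#' averaged over `n_randomizations` reshuffles: a real curve above the
#' baseline at small `k` means same-OD reactions cluster in the network.
#'
#' @param net a [reaction_network()] with OD.
#' @param max_k largest separation to report.
#' @param n_randomizations reshuffled replicates for the baseline; default 20.
#' @param od_bin_width OD values are compared after binning with this width;
#'   default 1 (exact OD equality).
#' @param rng_seed optional integer seed.
#' @return an object of class `od_correlation_profile`: `per_k` (data.frame
#'   `k`, `p_same`, `n_pairs`; distances with no pairs are omitted),
#'   `baseline_per_k` (data.frame `k`, `mean`, `sd`), `n_randomizations`,
#'   `rng_seed`.
#' @export
same_od_correlation <- function(net, max_k = 10L, n_randomizations = 20L,
                                od_bin_width = 1L, rng_seed = NULL) {
  stopifnot(inherits(net, "reaction_network"), max_k >= 1L,
            n_randomizations >= 1L)
  if (is.null(net$od)) stop("OD annotation required")
  g <- rn_igraph(net, directed = FALSE)
  D <- igraph::distances(g, mode = "all")[net$nodes, net$nodes]
  ut <- upper.tri(D)
  bin <- as.integer(ceiling(net$od[net$nodes] / od_bin_width))

  masks <- lapply(seq_len(max_k), function(k) ut & D == k)
  n_pairs <- vapply(masks, sum, numeric(1))
  keep <- n_pairs > 0
  p_same_at <- function(b) {
    S <- outer(b, b, "==")
    vapply(which(keep), function(k) sum(S[masks[[k]]]) / n_pairs[k], numeric(1))
  }
  p_real <- p_same_at(bin)
  null_mat <- with_seed(rng_seed, vapply(seq_len(n_randomizations), function(r) {
    p_same_at(sample(bin))
  }, numeric(sum(keep))))
  null_mat <- matrix(null_mat, nrow = sum(keep))

  ks <- which(keep)
  structure(
    list(per_k = data.frame(k = ks, p_same = p_real,
                            n_pairs = as.integer(n_pairs[keep])),
         baseline_per_k = data.frame(k = ks,
                                     mean = apply(null_mat, 1L, mean),
                                     sd = apply(null_mat, 1L, sd)),
         n_randomizations = as.integer(n_randomizations),
         rng_seed = rng_seed),
    class = "od_correlation_profile")
}

#' @export
print.od_correlation_profile <- function(x, ...) {
  df <- merge(x$per_k, x$baseline_per_k, by = "k")
  names(df)[names(df) == "mean"] <- "null_mean"
  names(df)[names(df) == "sd"] <- "null_sd"
  cat("same-OD correlation (", x$n_randomizations, "reshuffles )\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Histogram of organism degrees
#'
#' Counts of reactions per OD value in a union network.
#'
#' @param net a [reaction_network()] with OD.
#' @return data.frame with columns `od` and `count`.
#' @export
od_histogram <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  if (is.null(net$od)) stop("OD annotation required")
  tb <- table(factor(net$od, levels = seq_len(max(net$od))))
  data.frame(od = as.integer(names(tb)), count = as.integer(tb))
}

#' Write a distance or correlation profile as TSV
#'
#' @param profile an [od_vs_distance()] or [same_od_correlation()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  if (inherits(profile, "od_distance_profile")) {
    df <- profile$per_distance
  } else if (inherits(profile, "od_correlation_profile")) {
    df <- merge(profile$per_k, profile$baseline_per_k, by = "k")
    names(df) <- c("k", "p_same", "n_pairs", "baseline_mean", "baseline_sd")
  } else {
    stop("unsupported profile object")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
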