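#' Read a reaction table
#'
#' Reads the tab-separated reaction-table dialect used throughout the package:
#' a header line `reaction_id  substrates  products  organisms` followed by one
#' row per reaction, with the `substrates`, `products` and `organisms` fields
#' `;`-separated. A reversible reaction must be encoded as a single row in its
#' canonical direction; reaction ids are primary keys and may not repeat.
#'
#' @param path path to the TSV file.
#' @param require_organisms when `TRUE` (default) an empty `organisms` field is
#'   a format error; set to `FALSE` for background universes that carry no
#'   organism annotation (the file must then have the field empty on every
#'   row, and the returned network has `membership = NULL`).
#' @return a [bipartite_network()].
#' @export
read_reaction_table <- function(path, require_organisms = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  needed <- c("reaction_id", "substrates", "products", "organisms")
  if (!all(needed %in% names(df))) {
    stop("reaction table must have columns: ", paste(needed, collapse = ", "))
  }
  dup <- duplicated(df$reaction_id)
  if (any(dup)) {
    stop("duplicate reaction id '", df$reaction_id[dup][1L],
         "' at row ", which(dup)[1L])
  }
  split_field <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  subs <- split_field(df$substrates)
  prods <- split_field(df$products)
  orgs <- split_field(df$organisms)

  empty_org <- lengths(orgs) == 0L
  if (require_organisms && any(empty_org)) {
    stop("empty organism field at row ", which(empty_org)[1L])
  }
  membership <- NULL
  if (!all(empty_org)) {
    if (any(empty_org)) {
      stop("mixed empty/non-empty organism fields; first empty at row ",
           which(empty_org)[1L])
    }
    membership <- setNames(orgs, df$reaction_id)
  }

  link_df <- function(rids, mlists, rxn_first) {
    m <- unlist(mlists, use.names = FALSE)
    r <- rep(rids, lengths(mlists))
    if (rxn_first) data.frame(reaction = r, metabolite = m)
    else data.frame(metabolite = m, reaction = r)
  }
  mets <- unique(c(unlist(subs), unlist(prods)))
  bipartite_network(
    metabolites = mets,
    reactions = df$reaction_id,
    substrate_links = link_df(df$reaction_id, subs, rxn_first = FALSE),
    product_links = link_df(df$reaction_id, prods, rxn_first = TRUE),
    membership = membership
  )
}

#' Write a reaction table
#'
#' Inverse of [read_reaction_table()]; fields are written sorted so that a
#' write/read round trip reproduces the network exactly.
#'
#' @param net a [bipartite_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(net, path) {
  stopifnot(inherits(net, "bipartite_network"))
  join <- function(links, key, val) {
    sp <- split(links[[val]], links[[key]])
    out <- setNames(rep("", length(net$reactions)), net$reactions)
    out[names(sp)] <- vapply(sp, function(v) paste(sort(v), collapse = ";"), "")
    out
  }
  orgs <- setNames(rep("", length(net$reactions)), net$reactions)
  if (!is.null(net$membership)) {
    orgs[names(net$membership)] <-
      vapply(net$membership, paste, "", collapse = ";")
  }
  df <- data.frame(
    reaction_id = net$reactions,
    substrates = join(net$substrate_links, "reaction", "metabolite"),
    products = join(net$product_links, "reaction", "metabolite"),
    organisms = orgs
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove currency metabolites by a connectivity threshold
#'
#' Ubiquitous metabolites (water, ATP, NADH, ...) connect to so many reactions
#' that they would dominate the reaction-reaction projection. This drops every
#' metabolite whose total bipartite connectivity (substrate links plus product
#' links) is strictly greater than `threshold`, together with its links;
#' metabolites of connectivity exactly `threshold` survive. Reactions are
#' never removed. Pruning is applied before projection.
#'
#' @param net a [bipartite_network()].
#' @param threshold connectivity cutoff; default 10.
#' @return a new, pruned [bipartite_network()].
#' @export
prune_currency_metabolites <- function(net, threshold = 10) {
  stopifnot(inherits(net, "bipartite_network"), threshold >= 1)
  deg <- table(c(net$substrate_links$metabolite, net$product_links$metabolite))
  drop <- names(deg)[deg > threshold]
  keep_met <- setdiff(net$metabolites, drop)
  bipartite_network(
    metabolites = keep_met,
    reactions = net$reactions,
    substrate_links =
      net$substrate_links[net$substrate_links$metabolite %in% keep_met, ],
    product_links =
      net$product_links[net$product_links$metabolite %in% keep_met, ],
    membership = net$membership
  )
}

#' Project a bipartite metabolic network onto its reactions
#'
#' Builds the directed reaction-reaction network: an edge r1 -> r2 exists iff
#' some metabolite is a product of r1 and a substrate of r2. Self-loops (a
#' reaction feeding itself) are discarded and parallel edges collapsed. When
#' the bipartite network carries organism membership, each reaction node is
#' tagged with its organism degree.
#'
#' @param net a [bipartite_network()], normally after
#'   [prune_currency_metabolites()].
#' @return a [reaction_network()].
#' @export
project_to_reactions <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  if (nrow(net$product_links) > 0L && nrow(net$substrate_links) > 0L) {
    e <- merge(net$product_links, net$substrate_links, by = "metabolite")
    edges <- data.frame(from = e$reaction.x, to = e$reaction.y)
  } else {
    edges <- data.frame(from = character(0), to = character(0))
  }
  membership <- net$membership
  if (!is.null(membership)) {
    missing <- setdiff(net$reactions, names(membership))
    if (length(missing) > 0L) {
      stop("reaction with empty organism membership: ", missing[1L])
    }
  }
  reaction_network(net$reactions, edges, membership = membership)
}

#' Build the union network of many organisms
#'
#' Pools the reaction sets of several organisms on a common projected
#' universe: the node set is the union of the organism sets, edges are the
#' universe edges restricted to that set, and each node's organism degree
#' (OD) is the number of organisms containing it.
#'
#' @param organism_sets named list: organism id -> character vector of
#'   reaction ids.
#' @param universe_projection a [reaction_network()] containing every reaction
#'   referenced by `organism_sets`.
#' @return a [reaction_network()] with `od` and `membership` set.
#' @export
build_union <- function(organism_sets, universe_projection) {
  stopifnot(inherits(universe_projection, "reaction_network"),
            length(organism_sets) >= 1L, !is.null(names(organism_sets)))
  nodes <- sort(unique(unlist(organism_sets, use.names = FALSE)))
  unknown <- setdiff(nodes, universe_projection$nodes)
  if (length(unknown) > 0L) {
    stop("reaction not in universe projection: ", unknown[1L])
  }
  pairs <- data.frame(
    organism = rep(names(organism_sets), lengths(organism_sets)),
    reaction = unlist(organism_sets, use.names = FALSE)
  )
  membership <- lapply(split(pairs$organism, pairs$reaction), unique)
  e <- universe_projection$edges
  e <- e[e$from %in% nodes & e$to %in% nodes, , drop = FALSE]
  reaction_network(nodes, e, membership = membership)
}

#' Check that equal OD implies equal species sets among neighbours
#'
#' The OD compresses each reaction's full phylogenetic profile to one number.
#' As a sanity check on that compression, this measures how often two adjacent
#' reactions with the same OD are in fact carried by exactly the same set of
#' organisms.
#'
#' @param net a [reaction_network()] with membership annotation.
#' @return a list with `fraction` (concordant share among same-OD adjacent
#'   pairs; `NA` if there are none), `n_pairs`, and `discordant`, a data.frame
#'   of the offending pairs with their OD.
#' @export
od_species_consistency <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  if (is.null(net$membership)) stop("membership annotation required")
  pr <- undirected_pairs(net)
  same_od <- net$od[pr$a] == net$od[pr$b]
  pr <- pr[same_od, , drop = FALSE]
  if (nrow(pr) == 0L) {
    return(list(fraction = NA_real_, n_pairs = 0L,
                discordant = data.frame(a = character(0), b = character(0),
                                        od = integer(0))))
  }
  concordant <- vapply(seq_len(nrow(pr)), function(i) {
    identical(net$membership[[pr$a[i]]], net$membership[[pr$b[i]]])
  }, logical(1))
  disc <- pr[!concordant, , drop = FALSE]
  disc$od <- as.integer(net$od[disc$a])
  rownames(disc) <- NULL
  list(fraction = mean(concordant), n_pairs = nrow(pr), discordant = disc)
}

#' Export a reaction network
#'
#' `write_reaction_graphml()` writes GraphML with `od` as a node attribute
#' (when present); `write_edge_list()` writes a plain `from<TAB>to` table.
#'
#' @param net a [reaction_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reaction_graphml <- function(net, path) {
  g <- rn_igraph(net)
  if (!is.null(net$od)) {
    igraph::V(g)$od <- as.integer(net$od[igraph::V(g)$name])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_reaction_graphml
#' @export
write_edge_list <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
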