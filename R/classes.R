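#' Bipartite metabolite-reaction network
#'
#' The basic container for a metabolism: metabolite nodes, reaction nodes,
#' directed substrate links (metabolite -> reaction) and product links
#' (reaction -> metabolite), plus an optional membership map recording which
#' organisms carry each reaction. All components are canonicalised (sorted) so
#' that structurally equal networks are `identical()`.
#'
#' @param metabolites character vector of metabolite ids.
#' @param reactions character vector of reaction ids.
#' @param substrate_links data.frame with columns `metabolite`, `reaction`.
#' @param product_links data.frame with columns `reaction`, `metabolite`.
#' @param membership named list mapping reaction id -> character vector of
#'   organism ids, or `NULL` when organism annotation is absent (e.g. a
#'   background reaction universe).
#' @return an object of class `bipartite_network`.
#' @export
bipartite_network <- function(metabolites, reactions, substrate_links,
                              product_links, membership = NULL) {
  metabolites <- sort(unique(as.character(metabolites)))
  reactions <- sort(unique(as.character(reactions)))
  substrate_links <- canonical_links(substrate_links, c("metabolite", "reaction"))
  product_links <- canonical_links(product_links, c("reaction", "metabolite"))

  bad_s <- !(substrate_links$metabolite %in% metabolites) |
    !(substrate_links$reaction %in% reactions)
  bad_p <- !(product_links$metabolite %in% metabolites) |
    !(product_links$reaction %in% reactions)
  if (any(bad_s) || any(bad_p)) {
    stop("link endpoints must be declared metabolites and reactions")
  }
  if (!is.null(membership)) {
    if (is.null(names(membership)) || !all(names(membership) %in% reactions)) {
      stop("membership keys must be reaction ids")
    }
    if (any(lengths(membership) == 0L)) {
      stop("membership entries must name at least one organism")
    }
    membership <- lapply(membership, function(x) sort(unique(as.character(x))))
    membership <- membership[order(names(membership))]
  }
  structure(
    list(metabolites = metabolites, reactions = reactions,
         substrate_links = substrate_links, product_links = product_links,
         membership = membership),
    class = "bipartite_network"
  )
}

canonical_links <- function(df, cols) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(cols %in% names(df))) {
    stop("link table must have columns ", paste(cols, collapse = ", "))
  }
  df <- unique(df[cols])
  df[] <- lapply(df, as.character)
  df <- df[order(df[[1L]], df[[2L]]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("bipartite metabolic network\n")
  cat("  metabolites:", length(x$metabolites),
      " reactions:", length(x$reactions), "\n")
  cat("  substrate links:", nrow(x$substrate_links),
      " product links:", nrow(x$product_links), "\n")
  if (!is.null(x$membership)) {
    cat("  organisms:", length(unique(unlist(x$membership))), "\n")
  }
  invisible(x)
}

#' Directed reaction-reaction network with organism-degree annotation
#'
#' Nodes are reactions; a directed edge r1 -> r2 means some product of r1 is a
#' substrate of r2. Each node may carry an organism degree (OD), the number of
#' organisms whose metabolism contains the reaction, and optionally the full
#' organism membership set from which the OD is derived.
#'
#' @param nodes character vector of reaction ids.
#' @param edges data.frame with columns `from`, `to` (self-loops are dropped,
#'   parallel edges collapsed).
#' @param od named integer vector (names = reaction ids) or `NULL`. When
#'   `membership` is supplied, `od` is computed from it and must not conflict.
#' @param membership named list reaction id -> organism id vector, or `NULL`.
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(nodes, edges, od = NULL, membership = NULL) {
  nodes <- sort(unique(as.character(nodes)))
  edges <- canonical_links(edges, c("from", "to"))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  rownames(edges) <- NULL
  if (!all(edges$from %in% nodes) || !all(edges$to %in% nodes)) {
    stop("edge endpoints must be declared nodes")
  }
  if (!is.null(membership)) {
    if (!setequal(names(membership), nodes)) {
      stop("membership must cover exactly the node set")
    }
    if (any(lengths(membership) == 0L)) {
      stop("reaction with empty organism membership: OD undefined")
    }
    membership <- lapply(membership, function(x) sort(unique(as.character(x))))
    membership <- membership[nodes]
    od_m <- setNames(lengths(membership), nodes)
    if (!is.null(od)) {
      if (!identical(as.integer(od[nodes]), as.integer(od_m))) {
        stop("supplied od conflicts with membership sizes")
      }
    }
    od <- od_m
  } else if (!is.null(od)) {
    if (is.null(names(od)) || !setequal(names(od), nodes)) {
      stop("od must be named by the node set")
    }
    od <- setNames(as.integer(od[nodes]), nodes)
    if (any(is.na(od)) || any(od < 1L)) stop("od values must be integers >= 1")
  }
  structure(
    list(nodes = nodes, edges = edges, od = od, membership = membership),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction network:", length(x$nodes), "nodes,",
      nrow(x$edges), "directed edges\n")
  if (!is.null(x$od)) {
    cat("  OD range:", min(x$od), "-", max(x$od), "\n")
  }
  invisible(x)
}

# igraph view of a reaction network; isolated nodes kept.
rn_igraph <- function(net, directed = TRUE) {
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
  g
}

# undirected adjacency as a list of integer vectors indexed like net$nodes
rn_adjacency <- function(net) {
  n <- length(net$nodes)
  if (nrow(net$edges) == 0L) return(rep(list(integer(0)), n))
  fi <- match(net$edges$from, net$nodes)
  ti <- match(net$edges$to, net$nodes)
  a <- pmin(fi, ti)
  b <- pmax(fi, ti)
  key <- unique((a - 1) * n + b)
  a <- as.integer((key - 1) %/% n) + 1L
  b <- as.integer((key - 1) %% n) + 1L
  sp <- split(c(b, a), factor(c(a, b), levels = seq_len(n)))
  unname(lapply(sp, function(v) sort(v)))
}

# unique undirected node-id pairs (a < b lexicographically) that are adjacent
undirected_pairs <- function(net) {
  if (nrow(net$edges) == 0L) {
    return(data.frame(a = character(0), b = character(0)))
  }
  a <- pmin(net$edges$from, net$edges$to)
  b <- pmax(net$edges$from, net$edges$to)
  unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
}
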