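# Independent oracles and random-instance generators. Everything here is
# deliberately naive (matrix products, union-find, Floyd-Warshall-style path
# counting) and shares no code path with the package implementations.

random_bipartite <- function(n_reactions, n_metabolites, mean_links = 1.5) {
  rids <- sprintf("r%03d", seq_len(n_reactions))
  mids <- sprintf("m%03d", seq_len(n_metabolites))
  pick <- function() {
    k <- 1L + rpois(1L, mean_links - 1)
    sample(mids, min(k, n_metabolites))
  }
  subs <- lapply(rids, function(r) pick())
  prods <- lapply(rids, function(r) pick())
  bipartite_network(
    metabolites = mids, reactions = rids,
    substrate_links = data.frame(metabolite = unlist(subs),
                                 reaction = rep(rids, lengths(subs))),
    product_links = data.frame(reaction = rep(rids, lengths(prods)),
                               metabolite = unlist(prods)))
}

# projection oracle: incidence-matrix product. Edge r1 -> r2 iff
# (P S)[r1, r2] > 0 and r1 != r2, with P[r, m] = r produces m and
# S[m, r] = r consumes m.
oracle_projection_edges <- function(bp) {
  R <- bp$reactions
  M <- bp$metabolites
  P <- matrix(0L, length(R), length(M), dimnames = list(R, M))
  S <- matrix(0L, length(M), length(R), dimnames = list(M, R))
  P[cbind(bp$product_links$reaction, bp$product_links$metabolite)] <- 1L
  S[cbind(bp$substrate_links$metabolite, bp$substrate_links$reaction)] <- 1L
  A <- P %*% S
  diag(A) <- 0L
  idx <- which(A > 0, arr.ind = TRUE)
  e <- data.frame(from = R[idx[, 1L]], to = R[idx[, 2L]])
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  e
}

random_od_graph <- function(n_nodes, n_edges = 2L * n_nodes, max_od = 8L) {
  ids <- sprintf("n%03d", seq_len(n_nodes))
  from <- sample(ids, n_edges, replace = TRUE)
  to <- sample(ids, n_edges, replace = TRUE)
  keep <- from != to
  reaction_network(ids, data.frame(from = from[keep], to = to[keep]),
                   od = setNames(sample.int(max_od, n_nodes, replace = TRUE),
                                 ids))
}

# coarse-graining oracle: union-find over same-bin undirected edges
oracle_partition <- function(net, od_bin_width = 1L) {
  n <- length(net$nodes)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  bin <- ceiling(net$od[net$nodes] / od_bin_width)
  if (nrow(net$edges) > 0L) {
    fi <- match(net$edges$from, net$nodes)
    ti <- match(net$edges$to, net$nodes)
    for (k in seq_along(fi)) {
      if (bin[fi[k]] == bin[ti[k]]) {
        ra <- find(fi[k]); rb <- find(ti[k])
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(net$nodes, roots)
}

# canonical form of a partition: sorted, unnamed list of sorted member vectors
canonical_partition <- function(members) {
  members <- lapply(members, function(m) unname(sort(m)))
  unname(members[order(vapply(members, `[[`, "", 1L))])
}

# betweenness oracle: BFS shortest-path counts from every source, then the
# pair-sum of sigma_sv * sigma_vt / sigma_st over pairs with
# d(s,v) + d(v,t) = d(s,t).
oracle_betweenness <- function(net) {
  n <- length(net$nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(net$edges) > 0L) {
    fi <- match(net$edges$from, net$nodes)
    ti <- match(net$edges$to, net$nodes)
    for (k in seq_along(fi)) {
      a <- fi[k]; b <- ti[k]
      if (a != b) {
        adj[[a]] <- union(adj[[a]], b)
        adj[[b]] <- union(adj[[b]], a)
      }
    }
  }
  D <- matrix(Inf, n, n)
  SIG <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sig <- rep(0, n); sig[s] <- 1
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) sig[w] <- sig[w] + sig[v]
      }
    }
    D[s, ] <- dist
    SIG[s, ] <- sig
  }
  btw <- rep(0, n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    if (is.infinite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (D[s, v] + D[v, t] == D[s, t]) {
        btw[v] <- btw[v] + SIG[s, v] * SIG[v, t] / SIG[s, t]
      }
    }
  }
  setNames(btw, net$nodes)
}

# closed-form expectation of p_same(k) under a uniform OD permutation:
# P(two distinct positions get equal labels) = sum_o n_o (n_o - 1) / (N (N-1)),
# independent of k.
oracle_permutation_baseline <- function(od) {
  n <- length(od)
  f <- table(od)
  sum(f * (f - 1)) / (n * (n - 1))
}

# independent BFS component sweep on the undirected projection
component_sizes_bfs <- function(net) {
  n <- length(net$nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(net$edges) > 0L) {
    fi <- match(net$edges$from, net$nodes)
    ti <- match(net$edges$to, net$nodes)
    for (k in seq_along(fi)) {
      adj[[fi[k]]] <- union(adj[[fi[k]]], ti[k])
      adj[[ti[k]]] <- union(adj[[ti[k]]], fi[k])
    }
  }
  seen <- logical(n)
  sizes <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0L
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      size <- size + 1L
      nw <- adj[[v]][!seen[adj[[v]]]]
      seen[nw] <- TRUE
      queue <- c(queue, nw)
    }
    sizes <- c(sizes, size)
  }
  sizes
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# tiny chain universe for evolution tests: r1 -> r2 -> ... -> rn
chain_universe <- function(n) {
  rids <- sprintf("r%02d", seq_len(n))
  mids <- sprintf("m%02d", 0:n)
  bipartite_network(
    metabolites = mids, reactions = rids,
    substrate_links = data.frame(metabolite = mids[1:n], reaction = rids),
    product_links = data.frame(reaction = rids, metabolite = mids[2:(n + 1)]))
}
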