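# Incremental growth state over a fixed undirected adjacency list.
#
# `cnt[v]` is the number of in-set neighbours of v, maintained for every node:
# for out-of-set nodes cnt > 0 marks the frontier; for in-set nodes cnt == 1
# marks a leaf of the induced subgraph (whose removal cannot disconnect it).

gs_init <- function(adj, start) {
  n <- length(adj)
  st <- list(adj = adj, in_set = logical(n), cnt = integer(n), size = 0L)
  gs_add(st, start)
}

gs_add <- function(st, v) {
  st$in_set[v] <- TRUE
  st$size <- st$size + 1L
  nb <- st$adj[[v]]
  st$cnt[nb] <- st$cnt[nb] + 1L
  st
}

gs_remove <- function(st, v) {
  st$in_set[v] <- FALSE
  st$size <- st$size - 1L
  nb <- st$adj[[v]]
  st$cnt[nb] <- st$cnt[nb] - 1L
  st
}

gs_frontier <- function(st) which(!st$in_set & st$cnt > 0L)

gs_leaves <- function(st, protect = integer(0)) {
  lv <- which(st$in_set & st$cnt == 1L)
  setdiff(lv, protect)
}

#' Restrict a projected universe to a background for the growth model
#'
#' The neutral growth model runs on a background of all biochemically possible
#' reactions; following the analysis of real backgrounds, only the giant
#' (weakly) connected component is kept by default so any seed can in
#' principle reach any reaction.
#'
#' @param projection a [reaction_network()] (OD not required).
#' @param giant_component_only keep only the largest weakly connected
#'   component (default `TRUE`).
#' @return an object of class `background_network` wrapping the (possibly
#'   restricted) [reaction_network()].
#' @export
background_network <- function(projection, giant_component_only = TRUE) {
  stopifnot(inherits(projection, "reaction_network"))
  net <- projection
  if (giant_component_only && length(net$nodes) > 0L) {
    g <- rn_igraph(net)
    comp <- igraph::components(g, mode = "weak")
    keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
    e <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, ]
    net <- reaction_network(keep, e)
  }
  structure(list(net = net, giant_component_only = giant_component_only),
            class = "background_network")
}

#' @export
print.background_network <- function(x, ...) {
  cat("growth-model background:", length(x$net$nodes), "reactions,",
      nrow(x$net$edges), "links",
      if (x$giant_component_only) "(giant component)" else "", "\n")
  invisible(x)
}

#' Grow one network on the background
#'
#' The neutral growth model: starting from a single seed reaction, at each
#' time step with probability `p` a reaction is added, picked uniformly among
#' the background neighbours of the current set (biochemical compatibility is
#' the only constraint); with probability `1 - p` a uniformly chosen leaf of
#' the current induced subgraph (a reaction with exactly one link, counting in
#' and out together) is removed. The seed is never removed, and a removal step
#' with no available leaf is a no-op. The run stops when the set reaches
#' `target_size` or after `max_steps` steps. An addition step that finds the
#' frontier empty before `target_size` is reached raises a stalled-growth
#' error naming the achieved size.
#'
#' @param background a [background_network()].
#' @param seed_reaction reaction id to start from.
#' @param target_size requested final number of reactions.
#' @param p per-step probability of addition (0 < p <= 1); default 1, i.e.
#'   pure growth.
#' @param max_steps step budget; default `Inf`.
#' @param rng_seed optional integer seed.
#' @return an object of class `growth_run`: `params`, `final_set` (character
#'   vector of reaction ids), `steps_taken`.
#' @export
grow <- function(background, seed_reaction, target_size, p = 1,
                 max_steps = Inf, rng_seed = NULL) {
  stopifnot(inherits(background, "background_network"),
            p > 0, p <= 1, target_size >= 1)
  net <- background$net
  if (target_size > length(net$nodes)) {
    stop("target_size exceeds the background size")
  }
  start <- match(as.character(seed_reaction), net$nodes)
  if (is.na(start)) stop("seed reaction not in background: ", seed_reaction)

  adj <- rn_adjacency(net)
  run <- with_seed(rng_seed, {
    st <- gs_init(adj, start)
    steps <- 0L
    while (st$size < target_size && steps < max_steps) {
      steps <- steps + 1L
      if (p >= 1 || runif(1) < p) {
        fr <- gs_frontier(st)
        if (length(fr) == 0L) {
          stop(structure(
            class = c("odnet_stalled_growth", "error", "condition"),
            list(message = paste0("growth stalled at size ", st$size,
                                  " of requested ", target_size,
                                  ": frontier exhausted"),
                 call = sys.call(-1), achieved_size = st$size)))
        }
        st <- gs_add(st, sample1(fr))
      } else {
        lv <- gs_leaves(st, protect = start)
        if (length(lv) > 0L) st <- gs_remove(st, sample1(lv))
      }
    }
    list(set = net$nodes[st$in_set], steps = steps)
  })
  structure(
    list(params = list(seed_reaction = as.character(seed_reaction),
                       target_size = as.integer(target_size), p = p,
                       max_steps = max_steps, rng_seed = rng_seed),
         final_set = sort(run$set), steps_taken = run$steps),
    class = "growth_run")
}

#' @export
print.growth_run <- function(x, ...) {
  cat("growth run: seed", x$params$seed_reaction, "->",
      length(x$final_set), "reactions in", x$steps_taken, "steps\n")
  invisible(x)
}

#' Grow an ensemble of model organisms
#'
#' Runs the growth model once per requested size, mirroring the construction
#' of a model union whose individual network sizes match a set of organisms.
#' In `"fixed"` mode every run starts from the same `seed_reaction` (the
#' analogue of seeding from a reaction present in all organisms); in
#' `"random"` mode each run starts from a fresh uniformly drawn background
#' reaction. Per-run RNG streams are derived from `rng_seed` with
#' [derive_seeds()], so each run is independently reproducible. A stalled run
#' is recorded and the ensemble continues.
#'
#' @param background a [background_network()].
#' @param sizes integer vector of target sizes, one per run.
#' @param seed_mode `"fixed"` or `"random"`.
#' @param seed_reaction required in fixed mode.
#' @param p per-step addition probability; default 1.
#' @param rng_seed master integer seed; default `NULL` (current RNG stream).
#' @return an object of class `growth_ensemble`: `runs` (list of
#'   [grow()] results, `NULL` where stalled), `summary` data.frame (run id,
#'   seed reaction, target and achieved size, steps, status).
#' @export
generate_ensemble <- function(background, sizes, seed_mode = c("fixed", "random"),
                              seed_reaction = NULL, p = 1, rng_seed = NULL) {
  seed_mode <- match.arg(seed_mode)
  stopifnot(length(sizes) >= 1L)
  n_runs <- length(sizes)
  if (is.null(rng_seed)) rng_seed <- sample.int(.Machine$integer.max, 1L)
  run_seeds <- derive_seeds(rng_seed, n_runs + 1L)
  if (seed_mode == "fixed") {
    if (is.null(seed_reaction)) stop("fixed seed mode requires seed_reaction")
    seeds <- rep(as.character(seed_reaction), n_runs)
  } else {
    seeds <- with_seed(run_seeds[n_runs + 1L],
                       sample(background$net$nodes, n_runs, replace = TRUE))
  }
  runs <- vector("list", n_runs)
  status <- character(n_runs)
  achieved <- integer(n_runs)
  steps <- integer(n_runs)
  for (i in seq_len(n_runs)) {
    res <- tryCatch(
      grow(background, seeds[i], sizes[i], p = p, rng_seed = run_seeds[i]),
      odnet_stalled_growth = function(e) e)
    if (inherits(res, "growth_run")) {
      runs[[i]] <- res
      status[i] <- "ok"
      achieved[i] <- length(res$final_set)
      steps[i] <- res$steps_taken
    } else {
      status[i] <- "stalled"
      achieved[i] <- res$achieved_size
      steps[i] <- NA_integer_
    }
  }
  structure(
    list(runs = runs,
         summary = data.frame(run = sprintf("run%03d", seq_len(n_runs)),
                              seed_reaction = seeds,
                              target_size = as.integer(sizes),
                              achieved_size = achieved, steps = steps,
                              status = status),
         seed_mode = seed_mode, p = p, rng_seed = rng_seed),
    class = "growth_ensemble")
}

#' @export
print.growth_ensemble <- function(x, ...) {
  cat("growth ensemble:", nrow(x$summary), "runs (", x$seed_mode, "seed ),",
      sum(x$summary$status == "ok"), "completed\n")
  invisible(x)
}

#' Union network of a model ensemble
#'
#' Pools the runs of a [generate_ensemble()] exactly as organism metabolisms
#' are pooled: node set is the union of the final sets, edges are the
#' background edges restricted to it, and the OD of a reaction is the number
#' of runs containing it. The result feeds directly into [coarse_grain()] and
#' the structure statistics.
#'
#' @param ensemble a [generate_ensemble()] result (or a plain list of
#'   [grow()] runs).
#' @param background the [background_network()] the runs were grown on.
#' @return a [reaction_network()] with OD (and run ids as membership).
#' @export
model_union <- function(ensemble, background) {
  runs <- if (inherits(ensemble, "growth_ensemble")) ensemble$runs else ensemble
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0L) stop("no completed runs to pool")
  sets <- lapply(runs, `[[`, "final_set")
  names(sets) <- sprintf("run%03d", seq_along(sets))
  build_union(sets, background$net)
}

#' Serialize growth runs
#'
#' Runs (parameters + final sets) as JSON; ensemble summary as TSV.
#'
#' @param ensemble a [generate_ensemble()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(ensemble, path) {
  jsonlite::write_json(
    list(seed_mode = ensemble$seed_mode, p = ensemble$p,
         rng_seed = ensemble$rng_seed,
         runs = lapply(ensemble$runs, function(r) {
           if (is.null(r)) NULL else list(params = r$params,
                                          steps_taken = r$steps_taken,
                                          final_set = r$final_set)
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_json
#' @export
write_ensemble_summary <- function(ensemble, path) {
  write.table(ensemble$summary, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
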