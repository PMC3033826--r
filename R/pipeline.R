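#' Configuration for a full analysis run
#'
#' Exactly one data source must be given: either `reaction_table` (a TSV path,
#' optionally with `background_table` for the growth-model comparison) or
#' `synthetic` (a list of arguments for [generate_universe()] /
#' [evolve_organisms()]; the generated universe then doubles as the growth
#' background).
#'
#' @param reaction_table path to a reaction table TSV, or `NULL`.
#' @param background_table optional path to a background universe TSV.
#' @param synthetic optional list with elements `n_reactions`,
#'   `n_metabolites`, and optionally `mean_out_degree`, `chain_bias`,
#'   `n_organisms`, `root_genome_size`, `gain_rate`, `loss_rate`, `tree`.
#' @param prune_threshold currency-metabolite connectivity cutoff; default 10.
#' @param od_bin_width OD bin width(s) for coarse-graining; the first value
#'   drives the z-score, every value gets a core-size report. Default 1.
#' @param n_randomizations reshuffles for the z-score and correlation
#'   baseline; default 20.
#' @param max_k largest separation for the correlation function; default 10.
#' @param growth optional list enabling the growth-model comparison:
#'   `sizes` (integer vector or `"match"` for the organism set sizes),
#'   `seed_mode` (`"fixed"`/`"random"`), `seed_reaction` (default in fixed
#'   mode: the lexicographically smallest maximum-OD reaction of the union),
#'   `p` (default 1).
#' @param rng_seed master seed; fans out to per-stage streams.
#' @param out_dir optional output directory for artifacts and the JSON report.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(reaction_table = NULL, background_table = NULL,
                            synthetic = NULL, prune_threshold = 10,
                            od_bin_width = 1L, n_randomizations = 20L,
                            max_k = 10L, growth = NULL, rng_seed = 1L,
                            out_dir = NULL) {
  if (is.null(reaction_table) == is.null(synthetic)) {
    stop("exactly one of reaction_table / synthetic must be set")
  }
  stopifnot(prune_threshold >= 1, all(od_bin_width >= 1),
            n_randomizations >= 2, max_k >= 1)
  structure(
    list(reaction_table = reaction_table, background_table = background_table,
         synthetic = synthetic, prune_threshold = prune_threshold,
         od_bin_width = as.integer(od_bin_width),
         n_randomizations = as.integer(n_randomizations),
         max_k = as.integer(max_k), growth = growth,
         rng_seed = as.integer(rng_seed), out_dir = out_dir),
    class = "analysis_config")
}

#' Run the full structural-correlation analysis
#'
#' Executes, in order: data acquisition (synthetic generation or table
#' reading), currency-metabolite pruning, reaction projection, OD/species-set
#' consistency, coarse-graining with super-node z-score and core sizes (per
#' requested bin width), centre location, OD-vs-distance profile, two-node
#' same-OD correlation, OD histogram, and — when configured — the neutral
#' growth-model comparison analysed identically on the background. One master
#' seed fans out to named per-stage streams, so the same config and seed give
#' a byte-identical JSON report.
#'
#' @param config an [analysis_config()].
#' @return an `analysis_report` list (see the fields written to JSON); when
#'   `config$out_dir` is set, artifacts and `report.json` are written there.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seeds <- setNames(as.list(derive_seeds(config$rng_seed, 4L)),
                    c("synthetic", "zscore", "correlation", "growth"))

  # --- data -----------------------------------------------------------------
  dataset <- NULL
  if (!is.null(config$synthetic)) {
    sp <- config$synthetic
    universe <- generate_universe(
      n_reactions = sp$n_reactions, n_metabolites = sp$n_metabolites,
      mean_out_degree = sp$mean_out_degree %||% 1.2,
      chain_bias = sp$chain_bias %||% 0.8, rng_seed = seeds$synthetic)
    dataset <- evolve_organisms(
      universe, n_organisms = sp$n_organisms %||% 30L,
      root_genome_size = sp$root_genome_size,
      gain_rate = sp$gain_rate %||% 20, loss_rate = sp$loss_rate %||% 4,
      tree = sp$tree %||% "random", rng_seed = seeds$synthetic)
    bp_raw <- as_union_bipartite(dataset)
    background_bp <- universe
  } else {
    bp_raw <- read_reaction_table(config$reaction_table)
    background_bp <- if (!is.null(config$background_table)) {
      read_reaction_table(config$background_table, require_organisms = FALSE)
    }
  }

  # --- build ----------------------------------------------------------------
  bp <- prune_currency_metabolites(bp_raw, config$prune_threshold)
  net <- project_to_reactions(bp)
  consistency <- od_species_consistency(net)

  analyse_union <- function(un, seed_z, seed_c) {
    w0 <- config$od_bin_width[1L]
    sg <- coarse_grain(un, w0)
    zs <- tryCatch(
      supernode_zscore(un, w0, config$n_randomizations, rng_seed = seed_z),
      error = function(e) list(error = conditionMessage(e)))
    cores <- lapply(config$od_bin_width, function(w) {
      core_sizes(coarse_grain(un, w))
    })
    ctr <- central_node(un)
    list(
      n_nodes = length(un$nodes), n_edges = nrow(un$edges),
      supernode_sizes = size_histogram(sg),
      zscore = if (!is.null(zs$error)) zs else
        zs[c("mean_size", "null_mean", "null_sd", "z", "n_randomizations")],
      core_sizes = cores,
      center = unclass(ctr)[[1L]],
      center_unconditioned = attr(ctr, "unconditioned"),
      od_distance = od_vs_distance(un, ctr),
      od_correlation = same_od_correlation(
        un, max_k = config$max_k,
        n_randomizations = config$n_randomizations, rng_seed = seed_c),
      od_histogram = od_histogram(un))
  }

  union_stats <- analyse_union(net, seeds$zscore, seeds$correlation)

  # --- growth-model comparison ----------------------------------------------
  growth_stats <- NULL
  ensemble <- NULL
  if (!is.null(config$growth) && !is.null(background_bp)) {
    gw <- config$growth
    bg <- background_network(
      project_to_reactions(
        prune_currency_metabolites(background_bp, config$prune_threshold)))
    sizes <- gw$sizes
    if (is.null(sizes) || identical(sizes, "match")) {
      if (is.null(dataset)) stop("growth sizes = 'match' needs synthetic data")
      sizes <- lengths(dataset$organism_sets)
    }
    seed_mode <- gw$seed_mode %||% "fixed"
    seed_rxn <- gw$seed_reaction
    if (seed_mode == "fixed" && is.null(seed_rxn)) {
      # mirror the real recipe: seed with a reaction present in all organisms
      top <- net$nodes[net$od == max(net$od)]
      top <- top[top %in% bg$net$nodes]
      if (length(top) == 0L) stop("no maximum-OD reaction in the background")
      seed_rxn <- sort(top)[1L]
    }
    ensemble <- generate_ensemble(bg, sizes, seed_mode = seed_mode,
                                  seed_reaction = seed_rxn, p = gw$p %||% 1,
                                  rng_seed = seeds$growth)
    g_seeds <- derive_seeds(seeds$growth, 2L)
    growth_stats <- analyse_union(model_union(ensemble, bg),
                                  g_seeds[1L], g_seeds[2L])
    growth_stats$ensemble_summary <- ensemble$summary
    growth_stats$seed_mode <- seed_mode
    growth_stats$seed_reaction <- seed_rxn
  }

  report <- structure(
    list(
      provenance = list(
        package_version = as.character(utils::packageVersion("odnet")),
        config = config[setdiff(names(config), "out_dir")],
        stage_seeds = seeds),
      network = list(
        n_metabolites_raw = length(bp_raw$metabolites),
        n_metabolites_pruned = length(bp$metabolites),
        n_reactions = length(net$nodes),
        n_links = nrow(net$edges),
        n_organisms = length(unique(unlist(net$membership)))),
      consistency = consistency[c("fraction", "n_pairs")],
      union = union_stats,
      model = growth_stats),
    class = "analysis_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(dataset)) {
      write_dataset(dataset, file.path(config$out_dir, "data"))
    }
    write_reaction_graphml(net, file.path(config$out_dir, "union.graphml"))
    write_supernode_graphml(coarse_grain(net, config$od_bin_width[1L]),
                            file.path(config$out_dir, "supernodes.graphml"))
    write_profile_tsv(union_stats$od_distance,
                      file.path(config$out_dir, "od_vs_distance.tsv"))
    write_profile_tsv(union_stats$od_correlation,
                      file.path(config$out_dir, "od_correlation.tsv"))
    if (!is.null(ensemble)) {
      write_ensemble_summary(ensemble, file.path(config$out_dir, "ensemble.tsv"))
    }
    write_report_json(report, file.path(config$out_dir, "report.json"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis report as JSON
#'
#' @param report a [run_analysis()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# jsonlite serialises plain lists/data.frames predictably; drop S3 wrappers
strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, strip_classes))
  }
  x
}

#' Compare two analysis reports
#'
#' Per-distance difference of shell-mean OD between two reports (e.g. a real
#' or synthetic union against a model union grown on the same background),
#' truncated to the shared distance range, plus the total-variation divergence
#' of the two relative-OD histograms (OD rescaled by its maximum into ten
#' equal bins, so unions over different numbers of organisms/runs are
#' comparable). Purely descriptive; no significance claims.
#'
#' @param report_a,report_b [run_analysis()] reports.
#' @return a list with `per_distance` (data.frame `distance`, `mean_od_a`,
#'   `mean_od_b`, `diff` = a - b), `truncated` (flag), and
#'   `od_histogram_divergence`.
#' @export
compare_real_vs_model <- function(report_a, report_b) {
  pa <- report_a$union$od_distance$per_distance
  pb <- (report_b$model %||% report_b$union)$od_distance$per_distance
  shared <- intersect(pa$distance, pb$distance)
  if (length(shared) == 0L) stop("distance profiles share no distances")
  truncated <- length(shared) < max(length(pa$distance), length(pb$distance))
  if (truncated) {
    message("profiles truncated to shared distance range 0..", max(shared))
  }
  df <- data.frame(
    distance = shared,
    mean_od_a = pa$mean_od[match(shared, pa$distance)],
    mean_od_b = pb$mean_od[match(shared, pb$distance)])
  df$diff <- df$mean_od_a - df$mean_od_b

  rel_hist <- function(h) {
    rel <- rep(h$od / max(h$od), h$count)
    tabulate(pmin(ceiling(rel * 10), 10L), nbins = 10L) / sum(h$count)
  }
  ha <- rel_hist(report_a$union$od_histogram)
  hb <- rel_hist((report_b$model %||% report_b$union)$od_histogram)
  list(per_distance = df, truncated = truncated,
       od_histogram_divergence = sum(abs(ha - hb)) / 2)
}
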