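#' Declarative configuration of the full pipeline
#'
#' Bundles inputs (in-memory objects or file paths), walk parameters and all
#' selection thresholds in one place; every run writes a resolved snapshot of
#' it and stamps each output row with its hash, so any result table can be
#' traced to the exact configuration that produced it.
#'
#' @param network an `msnet`, or a named list/vector of the three layer paths
#'   (`ppi`, `annotation`, `hierarchy`) for [load_network()].
#' @param catalog a `herb_catalog`, or a named list/vector of the two
#'   association-table paths (`herb_ingredient`, `ingredient_target`).
#' @param disease a [disease_context()], or a path to a plain-text disease
#'   protein list (one id per line).
#' @param walk a [walk_parameters()].
#' @param thresholds list of selection thresholds; defaults:
#'   `p_cutoff = 0.05`, `min_significant_ingredients = 5`,
#'   `min_enrichment = 5`, `min_herbs_for_core = 3`, `top_n_targets = 50`,
#'   `subnetwork_k = 20`.
#' @param correlation correlation method, `"pearson"` or `"spearman"`.
#' @param rng_seed seed recorded for seeded stages (z-score null draws).
#' @param out_dir output directory for result tables.
#' @return Object of class `pipeline_config` with materialized inputs.
#' @export
pipeline_config <- function(network, catalog, disease,
                            walk = walk_parameters(),
                            thresholds = list(),
                            correlation = c("pearson", "spearman"),
                            rng_seed = 1L,
                            out_dir = "results") {
  if (!inherits(network, "msnet"))
    network <- load_network(network[["ppi"]], network[["annotation"]],
                            network[["hierarchy"]])
  if (!inherits(catalog, "herb_catalog"))
    catalog <- read_herb_catalog(catalog[["herb_ingredient"]],
                                 catalog[["ingredient_target"]])
  if (!inherits(disease, "disease_context")) {
    ids <- readLines(disease, warn = FALSE)
    disease <- disease_context("DISEASE", ids[nzchar(ids)])
  }
  if (is.null(disease$population_size))
    disease$population_size <- length(network_proteins(network))

  defaults <- list(p_cutoff = 0.05, min_significant_ingredients = 5L,
                   min_enrichment = 5, min_herbs_for_core = 3L,
                   top_n_targets = 50L, subnetwork_k = 20L, top_n_herbs = 10L)
  thresholds <- utils::modifyList(defaults, thresholds)

  cfg <- structure(
    list(network = network, catalog = catalog, disease = disease,
         walk = walk, thresholds = thresholds,
         correlation = match.arg(correlation),
         rng_seed = as.integer(rng_seed), out_dir = out_dir),
    class = "pipeline_config"
  )
  cfg
}

config_hash <- function(config) {
  rlang::hash(list(summarize_network(config$network),
                   config$network$edges,
                   config$catalog$herb_ingredient,
                   config$catalog$ingredient_target,
                   config$disease$proteins,
                   config$disease$population_size,
                   unclass(config$walk), config$thresholds,
                   config$correlation, config$rng_seed))
}

write_config_snapshot <- function(config, hash) {
  snap <- list(
    hash = hash,
    network = as.list(summarize_network(config$network)),
    n_herbs = length(config$catalog$herbs),
    disease = list(id = config$disease$id,
                   n_proteins = length(config$disease$proteins),
                   population_size = config$disease$population_size),
    walk = list(restart_probability = config$walk$restart_probability,
                weights = as.list(config$walk$weights),
                tolerance = config$walk$tolerance,
                max_iterations = config$walk$max_iterations),
    thresholds = config$thresholds,
    correlation = config$correlation,
    rng_seed = config$rng_seed
  )
  jsonlite::write_json(snap, file.path(config$out_dir, "config_snapshot.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

disease_seed_profile <- function(config, operator) {
  seeds <- seed_set(intersect(config$disease$proteins,
                              network_node_ids(config$network)))
  compute_diffusion_profile(config$network, seeds, config$walk,
                            operator = operator)
}

#' Rank all retained herbs against the disease
#'
#' Executes the herb arm of the pipeline: filter herbs with fewer than three
#' target-associated ingredients, seed each retained herb with its top
#' pathway-count targets, diffuse, score against the disease profile, rank,
#' flag prioritized herbs, and identify the core targets of the top-ranked
#' herbs. Writes `herb_ranking.csv`, `core_targets.csv` and a resolved
#' config snapshot under `config$out_dir`; fully deterministic for a fixed
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `ranking`, `core`, `filtered_catalog`,
#'   `disease_profile`, `profiles` and `hash`.
#' @export
run_rank_herbs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  write_config_snapshot(config, hash)
  th <- config$thresholds

  cat_f <- filter_herbs(config$catalog)
  if (length(cat_f$herbs) == 0L) stopf("rank-herbs: no herbs retained by filter")

  operator <- build_transition_matrix(config$network, config$walk)
  node_ids <- network_node_ids(config$network)
  target_sets <- lapply(setNames(cat_f$herbs, cat_f$herbs), function(h)
    herb_seed_targets(cat_f, h, n = th$top_n_targets))
  seedable <- vapply(target_sets,
                     function(tg) length(intersect(tg, node_ids)) > 0L,
                     logical(1))
  if (any(!seedable))
    message(sprintf("rank-herbs: %d herb(s) dropped (no targets mapped into the network): %s",
                    sum(!seedable),
                    paste(names(seedable)[!seedable], collapse = ", ")))
  target_sets <- target_sets[seedable]
  seed_sets <- lapply(target_sets, seed_set)
  profiles <- compute_diffusion_profiles(config$network, seed_sets,
                                         config$walk, operator = operator)
  dis_profile <- disease_seed_profile(config, operator)

  sig_counts <- count_significant_ingredients(
    cat_f, names(target_sets), config$disease, p_cutoff = th$p_cutoff)

  ranking <- rank_entities(
    profiles, target_sets, config$disease, dis_profile,
    thresholds = prioritization_thresholds(
      p_cutoff = th$p_cutoff, min_enrichment = th$min_enrichment,
      min_significant_ingredients = th$min_significant_ingredients),
    method = config$correlation,
    significant_ingredient_counts = sig_counts
  )
  ranking$overlap <- sprintf("%d/%d", ranking$overlap_k, ranking$n_targets)
  ranking$config_hash <- hash

  top_herbs <- head(ranking$entity, th$top_n_herbs)
  core <- core_targets(cat_f, top_herbs, min_herbs = th$min_herbs_for_core)
  if (nrow(core) > 0L) core$config_hash <- hash

  cols <- c("rank", "entity", "correlation_score", "overlap", "hypergeom_p",
            "p_adjusted", "enrichment", "n_significant_ingredients",
            "prioritized", "config_hash")
  write.csv(ranking[, cols], file.path(config$out_dir, "herb_ranking.csv"),
            row.names = FALSE)
  write.csv(core, file.path(config$out_dir, "core_targets.csv"),
            row.names = FALSE)
  invisible(list(ranking = ranking, core = core, filtered_catalog = cat_f,
                 disease_profile = dis_profile, profiles = profiles,
                 hash = hash))
}

#' Rank the ingredients of one herb against the disease
#'
#' Each ingredient is seeded with its full target set (overlap denominator
#' `n` = that set's size), diffused and scored like a herb. Writes
#' `ingredient_ranking_<herb>.csv`.
#'
#' @param config a [pipeline_config()].
#' @param herb herb id; must survive the ingredient-count filter.
#' @return Invisibly, the ranking data frame.
#' @export
run_rank_ingredients <- function(config, herb) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  cat_f <- filter_herbs(config$catalog)
  if (!herb %in% cat_f$herbs)
    stopf("herb '%s' not present after filtering", herb)

  node_ids <- network_node_ids(config$network)
  ings <- herb_ingredients(cat_f, herb)
  target_sets <- lapply(setNames(ings, ings),
                        function(i) ingredient_targets(cat_f, i))
  usable <- vapply(target_sets,
                   function(tg) length(intersect(tg, node_ids)) > 0L,
                   logical(1))
  if (!any(usable)) stopf("no ingredient of '%s' has targets in the network", herb)
  target_sets <- target_sets[usable]
  seed_sets <- lapply(target_sets, seed_set)

  operator <- build_transition_matrix(config$network, config$walk)
  profiles <- compute_diffusion_profiles(config$network, seed_sets,
                                         config$walk, operator = operator)
  dis_profile <- disease_seed_profile(config, operator)

  th <- config$thresholds
  ranking <- rank_entities(
    profiles, target_sets, config$disease, dis_profile,
    thresholds = prioritization_thresholds(
      p_cutoff = th$p_cutoff, min_enrichment = th$min_enrichment),
    method = config$correlation
  )
  ranking$herb <- herb
  ranking$overlap <- sprintf("%d/%d", ranking$overlap_k, ranking$n_targets)
  ranking$config_hash <- hash
  cols <- c("rank", "herb", "entity", "correlation_score", "overlap",
            "hypergeom_p", "p_adjusted", "enrichment", "prioritized",
            "config_hash")
  write.csv(ranking[, cols],
            file.path(config$out_dir,
                      sprintf("ingredient_ranking_%s.csv", herb)),
            row.names = FALSE)
  invisible(ranking)
}

#' Extract and export the mechanism subnetwork of one ingredient
#'
#' Computes the ingredient and disease diffusion profiles, builds the top-k
#' mechanism subnetwork, and writes `subnetwork_<ingredient>.sif`,
#' `.graphml` and a node-annotation CSV under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param ingredient ingredient id with at least one target in the network.
#' @return Invisibly, the `mechanism_subnetwork`.
#' @export
run_subnetwork <- function(config, ingredient) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  targets <- ingredient_targets(config$catalog, ingredient)
  targets <- intersect(targets, network_node_ids(config$network))
  if (length(targets) == 0L)
    stopf("ingredient '%s' has no targets in the network", ingredient)

  operator <- build_transition_matrix(config$network, config$walk)
  profile_ing <- compute_diffusion_profile(config$network, seed_set(targets),
                                           config$walk, operator = operator)
  profile_dis <- disease_seed_profile(config, operator)
  sub <- build_subnetwork(
    config$network, ingredient, targets, config$disease,
    profile_ing, profile_dis,
    params = subnetwork_parameters(k = config$thresholds$subnetwork_k))

  base <- file.path(config$out_dir, paste0("subnetwork_", ingredient))
  export_subnetwork(sub, paste0(base, ".sif"), "sif")
  export_subnetwork(sub, paste0(base, ".graphml"), "graphml")
  write.csv(subnetwork_annotation(sub), paste0(base, "_nodes.csv"),
            row.names = FALSE)
  invisible(sub)
}

#' Over-representation analysis of the pipeline's core targets
#'
#' Runs [over_representation()] for a target set (by default the core
#' targets of the top-ranked herbs from `herb_result`) against a gene-set
#' library, drops disease-specific terms, and writes `enrichment.csv`.
#'
#' @param config a [pipeline_config()].
#' @param library a [gene_set_library()].
#' @param targets gene ids to test; defaults to `herb_result$core$target`.
#' @param herb_result result of [run_rank_herbs()] (used only for the
#'   default `targets`).
#' @param background passed to [over_representation()].
#' @param exclusion_patterns disease-term patterns for
#'   [filter_disease_terms()].
#' @return Invisibly, the enrichment data frame.
#' @export
run_enrichment <- function(config, library, targets = NULL,
                           herb_result = NULL, background = NULL,
                           exclusion_patterns = character()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  targets <- targets %||% herb_result$core$target
  if (is.null(targets) || length(targets) == 0L)
    stopf("no targets to enrich; supply 'targets' or a herb_result with core targets")
  bg <- sort_ids(unique(c(background %||% unlist(library$sets, use.names = FALSE),
                          targets)))
  rec <- over_representation(targets, library, background = bg,
                             null_seed = config$rng_seed)
  rec <- filter_disease_terms(rec, exclusion_patterns)
  rec$overlap <- sprintf("%d/%d", rec$overlap_k, rec$set_size_m)
  rec$config_hash <- config_hash(config)
  write.csv(rec[, c("term", "overlap", "p_value", "adjusted_p", "odds_ratio",
                    "z_score", "combined_score", "config_hash")],
            file.path(config$out_dir, "enrichment.csv"), row.names = FALSE)
  invisible(rec)
}
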