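#' Configuration of the synthetic study generator
#'
#' The generator emulates the statistical structure of the real inputs the
#' pipeline consumes: a sparse scale-free protein-protein layer (preferential
#' attachment, so hub effects on the walk are represented), a rooted function
#' hierarchy with cross-links, sparse protein-function annotations, a
#' connected disease module, and a herb catalog in which a planted fraction
#' of herbs concentrates its ingredient targets in the graph neighborhood of
#' the disease module while background herbs draw targets uniformly.
#'
#' @param n_proteins,n_functions node counts for the two classes.
#' @param ppi_attachment edges added per new protein in the preferential-
#'   attachment layer (must be < `n_proteins`).
#' @param annotation_density expected annotations per protein.
#' @param hierarchy_branching expected function-function edges per function
#'   (a spanning tree plus uniform cross-links up to this density).
#' @param disease_module_size size of the connected disease protein module.
#' @param n_herbs number of herbs.
#' @param ingredients_per_herb integer range (min, max) of ingredients drawn
#'   per herb.
#' @param targets_per_ingredient integer range (min, max) of protein targets
#'   per ingredient.
#' @param planted_fraction fraction of herbs planted near the disease module.
#' @param proximity_hops planted targets are drawn from proteins within this
#'   graph distance of the disease module (1 = module plus direct
#'   interactors).
#' @param leakage fraction of a planted herb's targets drawn uniformly
#'   instead of from the proximity pool, so recovery is nontrivial.
#' @param rng_seed integer seed; all draws are deterministic given it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 800L, n_functions = 300L,
                             ppi_attachment = 2L, annotation_density = 2,
                             hierarchy_branching = 2,
                             disease_module_size = 15L, n_herbs = 60L,
                             ingredients_per_herb = c(3L, 8L),
                             targets_per_ingredient = c(1L, 8L),
                             planted_fraction = 0.2, proximity_hops = 1L,
                             leakage = 0.2, rng_seed = 1L) {
  assert_count(n_proteins, "n_proteins", 2L)
  assert_count(n_functions, "n_functions", 1L)
  assert_count(ppi_attachment, "ppi_attachment", 1L)
  if (ppi_attachment >= n_proteins)
    stopf("ppi_attachment must be < n_proteins")
  assert_count(disease_module_size, "disease_module_size", 1L)
  if (disease_module_size > n_proteins)
    stopf("disease_module_size exceeds n_proteins")
  assert_count(n_herbs, "n_herbs", 1L)
  stopifnot(length(ingredients_per_herb) == 2L,
            ingredients_per_herb[1] >= 1L,
            ingredients_per_herb[2] >= ingredients_per_herb[1],
            length(targets_per_ingredient) == 2L,
            targets_per_ingredient[1] >= 1L,
            targets_per_ingredient[2] >= targets_per_ingredient[1],
            annotation_density > 0, hierarchy_branching >= 1,
            planted_fraction >= 0, planted_fraction <= 1,
            leakage >= 0, leakage <= 1)
  assert_count(proximity_hops, "proximity_hops", 0L)
  assert_count(rng_seed, "rng_seed", 0L)
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_functions = as.integer(n_functions),
         ppi_attachment = as.integer(ppi_attachment),
         annotation_density = annotation_density,
         hierarchy_branching = hierarchy_branching,
         disease_module_size = as.integer(disease_module_size),
         n_herbs = as.integer(n_herbs),
         ingredients_per_herb = as.integer(ingredients_per_herb),
         targets_per_ingredient = as.integer(targets_per_ingredient),
         planted_fraction = planted_fraction,
         proximity_hops = as.integer(proximity_hops),
         leakage = leakage,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_config"
  )
}

# sample() treats a length-1 numeric first argument as 1:n; guard against it
sample_range <- function(lo, hi) if (lo == hi) lo else sample(lo:hi, 1L)

protein_ids <- function(n) sprintf("P%04d", seq_len(n))
function_ids <- function(n) sprintf("F%04d", seq_len(n))
herb_ids <- function(n) sprintf("H%03d", seq_len(n))

#' Generate a synthetic multiscale interactome
#'
#' Deterministic given `config$rng_seed`. The PPI layer is a connected
#' preferential-attachment graph; the function layer is a rooted spanning
#' tree (rows child -> parent) plus uniform cross-links up to the configured
#' branching density; annotations are uniform protein-function pairs at the
#' configured density.
#'
#' @param config a [synthetic_config()].
#' @return An `msnet`.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$rng_seed, generate_network_impl(config))
}

generate_network_impl <- function(config) {
  np <- config$n_proteins; nf <- config$n_functions
  prots <- protein_ids(np); funs <- function_ids(nf)

  g <- igraph::sample_pa(np, m = config$ppi_attachment, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  ppi <- data.frame(from = prots[el[, 1L]], to = prots[el[, 2L]])

  # spanning tree: function i (i >= 2) attaches to a uniformly chosen earlier
  # function as its parent; cross-links add further child -> parent pairs
  hier <- NULL
  if (nf >= 2L) {
    parent <- vapply(2:nf, function(i) sample.int(i - 1L, 1L), integer(1))
    hier <- data.frame(from = funs[2:nf], to = funs[parent])
    n_cross <- max(0L, round(config$hierarchy_branching * nf) - (nf - 1L))
    if (n_cross > 0L) {
      ci <- sample.int(nf, n_cross, replace = TRUE)
      cj <- sample.int(nf, n_cross, replace = TRUE)
      keep <- ci != cj
      cross <- data.frame(from = funs[pmax(ci, cj)[keep]],
                          to = funs[pmin(ci, cj)[keep]])
      hier <- rbind(hier, cross)
    }
  }

  n_ann <- round(config$annotation_density * np)
  ann <- data.frame(from = prots[sample.int(np, n_ann, replace = TRUE)],
                    to = funs[sample.int(nf, n_ann, replace = TRUE)])

  multiscale_network(ppi = ppi, annotation = ann, hierarchy = hier,
                     proteins = prots, functions = funs)
}

#' Generate a full synthetic study with planted signal
#'
#' Produces a network, a connected disease module, a herb catalog and the
#' ground truth. Planted herbs draw each ingredient target from the proteins
#' within `proximity_hops` of the disease module with probability
#' `1 - leakage` (uniformly otherwise); background herbs draw uniformly from
#' all proteins. Every planted herb is guaranteed at least one target inside
#' the proximity pool. Ingredient ids are unique per herb.
#'
#' @param config a [synthetic_config()].
#' @return List with elements `network` (`msnet`), `disease`
#'   ([disease_context()]), `catalog` ([herb_catalog()]) and `truth` (list
#'   with `planted` herb ids and `disease_proteins`).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$rng_seed, {
    net <- generate_network_impl(config)
    prots <- network_proteins(net)
    np <- length(prots)

    g <- igraph::graph_from_data_frame(
      network_edges(net, "ppi")[, c("from", "to")],
      directed = FALSE, vertices = data.frame(name = prots))

    # connected disease module: BFS from a random protein
    start <- sample(prots, 1L)
    bfs_order <- igraph::as_ids(igraph::bfs(g, root = start, order = TRUE)$order)
    module <- bfs_order[seq_len(config$disease_module_size)]

    pool <- if (config$proximity_hops == 0L) module else {
      unique(unlist(lapply(
        igraph::ego(g, order = config$proximity_hops, nodes = module),
        function(v) v$name)))
    }

    n_planted <- round(config$planted_fraction * config$n_herbs)
    herbs <- herb_ids(config$n_herbs)
    planted <- if (n_planted > 0L) sort_ids(sample(herbs, n_planted)) else character()

    hi <- list(); it <- list()
    ing_counter <- 0L
    for (h in herbs) {
      n_ing <- sample_range(config$ingredients_per_herb[1L],
                            config$ingredients_per_herb[2L])
      is_planted <- h %in% planted
      got_pool_target <- FALSE
      for (j in seq_len(n_ing)) {
        ing_counter <- ing_counter + 1L
        ing <- sprintf("I%05d", ing_counter)
        hi[[length(hi) + 1L]] <- data.frame(herb = h, ingredient = ing)
        n_t <- sample_range(config$targets_per_ingredient[1L],
                            config$targets_per_ingredient[2L])
        if (is_planted) {
          from_pool <- stats::runif(n_t) >= config$leakage
          tg <- character(n_t)
          if (any(from_pool))
            tg[from_pool] <- sample(pool, sum(from_pool), replace = TRUE)
          if (any(!from_pool))
            tg[!from_pool] <- sample(prots, sum(!from_pool), replace = TRUE)
          got_pool_target <- got_pool_target || any(from_pool)
          if (j == n_ing && !got_pool_target) tg[1L] <- sample(pool, 1L)
        } else {
          tg <- sample(prots, n_t, replace = TRUE)
        }
        it[[length(it) + 1L]] <- data.frame(ingredient = ing,
                                            target = unique(tg))
      }
    }
    catalog <- herb_catalog(do.call(rbind, hi), do.call(rbind, it))
    disease <- disease_context("DISEASE", module, population_size = np)
    list(network = net, disease = disease, catalog = catalog,
         truth = list(planted = planted, disease_proteins = sort_ids(module)))
  })
}

#' Write a synthetic study to the pipeline's on-disk formats
#'
#' Emits the three network layer TSVs, the two catalog TSVs and the disease
#' protein list, i.e. exactly what [load_network()], [read_herb_catalog()]
#' and a plain `readLines()` consume.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, named vector of the written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ppi = file.path(dir, "ppi.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    hierarchy = file.path(dir, "hierarchy.tsv"),
    herb_ingredient = file.path(dir, "herb_ingredient.tsv"),
    ingredient_target = file.path(dir, "ingredient_target.tsv"),
    disease = file.path(dir, "disease_proteins.txt")
  )
  write_network(study$network, paths["ppi"], paths["annotation"],
                paths["hierarchy"])
  write_herb_catalog(study$catalog, paths["herb_ingredient"],
                     paths["ingredient_target"])
  writeLines(study$disease$proteins, paths["disease"])
  invisible(paths)
}
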