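#' Disease context for prioritization
#'
#' @param id disease identifier (free text).
#' @param proteins character vector of disease-associated protein ids; its
#'   cardinality is the hypergeometric `K`.
#' @param population_size hypergeometric population `N`: the number of
#'   proteins eligible as targets. Defaults (at use sites) to the protein
#'   count of the network.
#' @return Object of class `disease_context`.
#' @export
disease_context <- function(id, proteins, population_size = NULL) {
  proteins <- sort_ids(unique(as.character(proteins)))
  if (length(proteins) < 1L) stopf("disease context needs >= 1 protein")
  if (!is.null(population_size)) {
    assert_count(population_size, "population_size", min = 1L)
    if (population_size < length(proteins))
      stopf("population_size (%d) smaller than number of disease proteins (%d)",
            population_size, length(proteins))
  }
  structure(list(id = as.character(id), proteins = proteins,
                 population_size = population_size),
            class = "disease_context")
}

disease_population <- function(disease, net = NULL) {
  disease$population_size %||% length(network_proteins(net))
}

#' Correlation between two diffusion profiles
#'
#' Profiles are aligned on the union of their node universes (missing entries
#' 0) before computing the correlation; this is the similarity score used to
#' rank herbs and ingredients against the disease.
#'
#' @param a,b `diffusion_profile` objects.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param exclude_seeds if TRUE, nodes seeding either profile are dropped
#'   from the aligned vectors before correlating.
#' @return Correlation in \[-1, 1\].
#' @export
correlation_score <- function(a, b, method = c("pearson", "spearman"),
                              exclude_seeds = FALSE) {
  stopifnot(inherits(a, "diffusion_profile"), inherits(b, "diffusion_profile"))
  method <- match.arg(method)
  ids <- sort_ids(union(names(a$freq), names(b$freq)))
  va <- setNames(numeric(length(ids)), ids)
  vb <- va
  va[names(a$freq)] <- a$freq
  vb[names(b$freq)] <- b$freq
  if (exclude_seeds) {
    drop <- ids %in% c(names(a$seeds), names(b$seeds))
    va <- va[!drop]; vb <- vb[!drop]
  }
  if (sd(va) == 0 || sd(vb) == 0)
    stopf("correlation undefined: a profile has zero variance")
  cor(va, vb, method = method)
}

#' Upper-tail hypergeometric overlap p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a random
#' size-`n` draw from a population of `N` proteins containing `K` disease
#' proteins overlaps the disease set in at least `k` proteins.
#'
#' @param k observed overlap.
#' @param n size of the entity's target set (draw size).
#' @param K number of disease proteins in the population.
#' @param N population size.
#' @return p-value in (0, 1].
#' @export
hypergeometric_overlap <- function(k, n, K, N) {
  k <- assert_count(k, "k"); n <- assert_count(n, "n")
  K <- assert_count(K, "K"); N <- assert_count(N, "N")
  if (n > N || K > N || k > n || k > K)
    stopf("infeasible hypergeometric counts: k=%d n=%d K=%d N=%d", k, n, K, N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fold enrichment of an overlap over its background fraction
#'
#' `(k/n) / p0` where `p0` is the background probability that a target is a
#' disease protein, either given directly or computed as `K/N`.
#'
#' @inheritParams hypergeometric_overlap
#' @param background_fraction `p0` directly; overrides `K`/`N` when given.
#' @return Nonnegative fold enrichment.
#' @export
enrichment_value <- function(k, n, K = NULL, N = NULL,
                             background_fraction = NULL) {
  k <- assert_count(k, "k")
  n <- assert_count(n, "n", min = 1L)
  p0 <- background_fraction
  if (is.null(p0)) {
    if (is.null(K) || is.null(N)) stopf("supply K and N or background_fraction")
    K <- assert_count(K, "K", min = 1L)
    N <- assert_count(N, "N", min = 1L)
    p0 <- K / N
  }
  if (!is.numeric(p0) || p0 <= 0) stopf("background fraction must be > 0")
  (k / n) / p0
}

#' Prioritization thresholds
#'
#' Defaults mirror the pipeline's selection rules: raw hypergeometric
#' p < 0.05, fold enrichment >= 5, and (for herbs) at least 5 ingredients
#' whose own target sets overlap the disease proteins significantly.
#'
#' @param p_cutoff raw p-value cutoff.
#' @param min_enrichment minimum fold enrichment.
#' @param min_significant_ingredients herb-level ingredient-support floor.
#' @return List of thresholds.
#' @export
prioritization_thresholds <- function(p_cutoff = 0.05, min_enrichment = 5,
                                      min_significant_ingredients = 5L) {
  stopifnot(p_cutoff > 0, min_enrichment >= 0)
  list(p_cutoff = p_cutoff, min_enrichment = min_enrichment,
       min_significant_ingredients = as.integer(min_significant_ingredients))
}

#' Rank herbs or ingredients against a disease diffusion profile
#'
#' For each entity the record carries the correlation score between its
#' diffusion profile and the disease profile, the overlap `k/n` of its target
#' list with the disease proteins, the upper-tail hypergeometric p-value of
#' that overlap, its fold enrichment, and a `prioritized` flag. A record is
#' prioritized iff `p < p_cutoff` and `enrichment >= min_enrichment` and --
#' when ingredient-support counts are supplied (herb ranking) -- at least
#' `min_significant_ingredients` of the entity's ingredients are individually
#' significant. BH-adjusted p-values are emitted alongside the raw ones for
#' transparency; the flag uses the raw cutoff.
#'
#' @param profiles named list of `diffusion_profile`s, one per entity.
#' @param target_sets named list of character vectors: the target list whose
#'   size is the overlap denominator `n` (top-50 list for herbs, full target
#'   set for ingredients).
#' @param disease a [disease_context()].
#' @param disease_profile `diffusion_profile` of the disease proteins.
#' @param thresholds a [prioritization_thresholds()].
#' @param method correlation method, passed to [correlation_score()].
#' @param significant_ingredient_counts optional named integer vector (herbs
#'   only): number of significantly disease-associated ingredients per herb,
#'   e.g. from [count_significant_ingredients()].
#' @param population_size hypergeometric `N`; defaults to the universe size
#'   of the disease profile restricted to proteins is not knowable here, so
#'   callers normally pass the network protein count via
#'   [disease_context()]'s `population_size` or this argument.
#' @return Data frame of ranking records sorted by correlation score
#'   descending (ties by entity id), invariant to the input order of
#'   entities.
#' @export
rank_entities <- function(profiles, target_sets, disease, disease_profile,
                          thresholds = prioritization_thresholds(),
                          method = "pearson",
                          significant_ingredient_counts = NULL,
                          population_size = NULL) {
  stopifnot(inherits(disease, "disease_context"),
            inherits(disease_profile, "diffusion_profile"))
  entities <- sort_ids(names(profiles))
  if (!setequal(entities, names(target_sets)))
    stopf("profiles and target_sets must name the same entities")
  N <- population_size %||% disease$population_size
  if (is.null(N)) stopf("population size N unavailable; set it on the disease context")
  K <- length(disease$proteins)

  rows <- lapply(entities, function(ent) {
    targets <- unique(target_sets[[ent]])
    n <- length(targets)
    k <- length(intersect(targets, disease$proteins))
    data.frame(
      entity = ent,
      correlation_score = correlation_score(profiles[[ent]], disease_profile,
                                            method = method),
      n_targets = n,
      overlap_k = k,
      hypergeom_p = if (n > 0L) hypergeometric_overlap(k, n, K, N) else 1,
      enrichment = if (n > 0L) enrichment_value(k, n, K, N) else 0
    )
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$hypergeom_p, method = "BH")
  if (!is.null(significant_ingredient_counts)) {
    out$n_significant_ingredients <-
      as.integer(significant_ingredient_counts[out$entity])
    out$n_significant_ingredients[is.na(out$n_significant_ingredients)] <- 0L
  } else {
    out$n_significant_ingredients <- NA_integer_
  }
  out$prioritized <- out$hypergeom_p < thresholds$p_cutoff &
    out$enrichment >= thresholds$min_enrichment &
    (is.null(significant_ingredient_counts) |
       out$n_significant_ingredients >= thresholds$min_significant_ingredients)
  out <- out[order_by_score(out$correlation_score, out$entity), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Count a herb's ingredients significantly associated with the disease
#'
#' An ingredient is significant when the upper-tail hypergeometric p-value of
#' the overlap between its full target set and the disease proteins is below
#' `p_cutoff`.
#'
#' @param catalog a `herb_catalog`.
#' @param herbs herb ids to evaluate.
#' @param disease a [disease_context()].
#' @param population_size hypergeometric `N` (defaults to the context's).
#' @param p_cutoff significance cutoff (default 0.05).
#' @return Named integer vector over `herbs`.
#' @export
count_significant_ingredients <- function(catalog, herbs, disease,
                                          population_size = NULL,
                                          p_cutoff = 0.05) {
  N <- population_size %||% disease$population_size
  if (is.null(N)) stopf("population size N unavailable")
  K <- length(disease$proteins)
  ing_sig <- new.env(parent = emptyenv())
  is_sig <- function(ing) {
    if (!is.null(ing_sig[[ing]])) return(ing_sig[[ing]])
    targets <- ingredient_targets(catalog, ing)
    p <- if (length(targets) == 0L) 1 else
      hypergeometric_overlap(length(intersect(targets, disease$proteins)),
                             length(targets), K, N)
    ing_sig[[ing]] <- p < p_cutoff
    ing_sig[[ing]]
  }
  setNames(vapply(herbs, function(h) {
    sum(vapply(herb_ingredients(catalog, h), is_sig, logical(1)))
  }, integer(1)), herbs)
}

#' Core protein targets of a set of top-ranked herbs
#'
#' Proteins targeted (through any ingredient, full target sets) by at least
#' `min_herbs` of the given herbs, with the count of herbs hitting each.
#'
#' @param catalog a `herb_catalog`.
#' @param top_herbs herb ids (must exist in the catalog).
#' @param min_herbs minimum number of herbs (default 3).
#' @return Data frame (`target`, `n_herbs`) sorted by count descending, ties
#'   by target id.
#' @export
core_targets <- function(catalog, top_herbs, min_herbs = 3L) {
  stopifnot(inherits(catalog, "herb_catalog"))
  assert_count(min_herbs, "min_herbs", min = 1L)
  per_herb <- lapply(top_herbs, function(h) unique(herb_targets(catalog, h)))
  tab <- table(unlist(per_herb))
  keep <- tab[tab >= min_herbs]
  out <- data.frame(target = names(keep), n_herbs = as.integer(keep))
  out <- out[order_by_score(out$n_herbs, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
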