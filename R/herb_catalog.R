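#' Herb-ingredient-target catalog
#'
#' Holds herb to ingredient associations and ingredient to protein-target
#' interactions, the raw material for seeding diffusion profiles. Pairs are
#' deduplicated; entities are declared implicitly by the pairs they appear in.
#'
#' @param herb_ingredient two-column data frame (herb id, ingredient id).
#' @param ingredient_target two-column data frame (ingredient id, protein id).
#' @return Object of class `herb_catalog` with elements `herbs`,
#'   `ingredients`, `herb_ingredient`, `ingredient_target`.
#' @export
herb_catalog <- function(herb_ingredient, ingredient_target) {
  hi <- data.frame(herb = as.character(herb_ingredient[[1L]]),
                   ingredient = as.character(herb_ingredient[[2L]]))
  it <- data.frame(ingredient = as.character(ingredient_target[[1L]]),
                   target = as.character(ingredient_target[[2L]]))
  if (nrow(hi) > 0L)
    hi <- hi[!duplicated(paste0(hi$herb, "\r", hi$ingredient)), , drop = FALSE]
  if (nrow(it) > 0L)
    it <- it[!duplicated(paste0(it$ingredient, "\r", it$target)), , drop = FALSE]
  rownames(hi) <- rownames(it) <- NULL
  structure(
    list(
      herbs = sort_ids(unique(hi$herb)),
      ingredients = sort_ids(unique(c(hi$ingredient, it$ingredient))),
      herb_ingredient = hi,
      ingredient_target = it
    ),
    class = "herb_catalog"
  )
}

#' Read a catalog from two TSV association tables
#'
#' Both files are tab-separated with at least two columns; `#` comment lines
#' are skipped, extra columns ignored.
#'
#' @param herb_ingredient_path TSV of (herb, ingredient) rows.
#' @param ingredient_target_path TSV of (ingredient, protein) rows.
#' @return A [herb_catalog()].
#' @export
read_herb_catalog <- function(herb_ingredient_path, ingredient_target_path) {
  herb_catalog(read_edge_tsv(herb_ingredient_path),
               read_edge_tsv(ingredient_target_path))
}

#' @rdname read_herb_catalog
#' @param catalog a `herb_catalog`.
#' @export
write_herb_catalog <- function(catalog, herb_ingredient_path,
                               ingredient_target_path) {
  stopifnot(inherits(catalog, "herb_catalog"))
  write.table(catalog$herb_ingredient, herb_ingredient_path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(catalog$ingredient_target, ingredient_target_path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(herb_ingredient_path, ingredient_target_path))
}

#' @export
print.herb_catalog <- function(x, ...) {
  cat(sprintf(
    "herb catalog: %d herbs, %d ingredients, %d herb-ingredient pairs, %d ingredient-target pairs\n",
    length(x$herbs), length(x$ingredients),
    nrow(x$herb_ingredient), nrow(x$ingredient_target)))
  invisible(x)
}

targeted_ingredients <- function(catalog) unique(catalog$ingredient_target$ingredient)

#' Ingredients of a herb / targets of an ingredient or herb
#'
#' `herb_targets()` returns the union of the full target sets of a herb's
#' ingredients.
#'
#' @param catalog a `herb_catalog`.
#' @param herb,ingredient entity id.
#' @return Character vector of ids (radix-sorted).
#' @export
herb_ingredients <- function(catalog, herb) {
  stopifnot(inherits(catalog, "herb_catalog"))
  if (!herb %in% catalog$herbs) stopf("unknown herb id: %s", herb)
  sort_ids(catalog$herb_ingredient$ingredient[catalog$herb_ingredient$herb == herb])
}

#' @rdname herb_ingredients
#' @export
ingredient_targets <- function(catalog, ingredient) {
  stopifnot(inherits(catalog, "herb_catalog"))
  if (!ingredient %in% catalog$ingredients)
    stopf("unknown ingredient id: %s", ingredient)
  sort_ids(catalog$ingredient_target$target[
    catalog$ingredient_target$ingredient == ingredient])
}

#' @rdname herb_ingredients
#' @export
herb_targets <- function(catalog, herb) {
  ings <- herb_ingredients(catalog, herb)
  sort_ids(unique(catalog$ingredient_target$target[
    catalog$ingredient_target$ingredient %in% ings]))
}

#' Drop herbs with fewer than `min_ingredients` target-associated ingredients
#'
#' A target-associated ingredient is one with at least one protein target in
#' the catalog. Removed herb ids are recorded in the `removed_herbs`
#' attribute of the result. Idempotent.
#'
#' @param catalog a `herb_catalog`.
#' @param min_ingredients retention threshold (default 3).
#' @return Filtered `herb_catalog`.
#' @export
filter_herbs <- function(catalog, min_ingredients = 3L) {
  stopifnot(inherits(catalog, "herb_catalog"))
  assert_count(min_ingredients, "min_ingredients", min = 1L)
  targeted <- targeted_ingredients(catalog)
  hi <- catalog$herb_ingredient
  n_targeted <- vapply(
    split(hi$ingredient, hi$herb),
    function(ings) sum(ings %in% targeted), integer(1)
  )
  keep <- names(n_targeted)[n_targeted >= min_ingredients]
  removed <- setdiff(catalog$herbs, keep)
  out <- herb_catalog(hi[hi$herb %in% keep, , drop = FALSE],
                      catalog$ingredient_target)
  attr(out, "removed_herbs") <- sort_ids(removed)
  out
}

#' Simple pathway counts for one herb
#'
#' For each protein targeted by at least one of the herb's ingredients, the
#' pathway count is the number of distinct ingredients of that herb targeting
#' it, so proteins hit convergently by several components rank above proteins
#' hit once.
#'
#' @param catalog a `herb_catalog`.
#' @param herb herb id present in the catalog.
#' @return Data frame (`target`, `pathway_count`) sorted by count descending,
#'   ties by target id ascending.
#' @export
herb_pathway_counts <- function(catalog, herb) {
  ings <- herb_ingredients(catalog, herb)
  it <- catalog$ingredient_target
  it <- it[it$ingredient %in% ings, , drop = FALSE]
  if (nrow(it) == 0L)
    return(data.frame(target = character(), pathway_count = integer()))
  tab <- table(it$target)
  out <- data.frame(target = names(tab), pathway_count = as.integer(tab))
  out <- out[order_by_score(out$pathway_count, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top targets of a herb by pathway count
#'
#' @param counts data frame from [herb_pathway_counts()].
#' @param n maximum number of targets to keep (default 50). Ties at the
#'   cutoff are broken by ascending protein id; if fewer than `n` targets
#'   exist, all are returned.
#' @return Ordered character vector of protein ids.
#' @export
top_targets <- function(counts, n = 50L) {
  assert_count(n, "n", min = 1L)
  ord <- order_by_score(counts$pathway_count, counts$target)
  counts$target[ord][seq_len(min(n, nrow(counts)))]
}

#' @rdname top_targets
#' @param catalog,herb catalog and herb id; convenience wrapper computing the
#'   pathway counts first. This top-target list is the herb's seed set for
#'   diffusion.
#' @export
herb_seed_targets <- function(catalog, herb, n = 50L) {
  top_targets(herb_pathway_counts(catalog, herb), n = n)
}
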