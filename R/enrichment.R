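#' Gene-set library
#'
#' @param sets named list of character vectors (term -> gene ids); empty sets
#'   are rejected.
#' @param source free-text label of the library's origin.
#' @return Object of class `gene_set_library`.
#' @export
gene_set_library <- function(sets, source = "custom") {
  if (length(sets) == 0L) stopf("library has no gene sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == ""))
    stopf("gene sets must have unique nonempty term names")
  sets <- lapply(sets, function(g) sort_ids(unique(as.character(g))))
  if (any(lengths(sets) == 0L)) stopf("gene sets must be nonempty")
  structure(list(sets = sets, source = as.character(source)),
            class = "gene_set_library")
}

#' Read / write a gene-set library in GMT format
#'
#' GMT: one set per line, tab-separated: term, description, then gene ids.
#'
#' @param path GMT file path.
#' @param source label recorded on the library (defaults to the file name).
#' @return [gene_set_library()] for `read_gmt()`; the path (invisibly) for
#'   `write_gmt()`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stopf("GMT line(s) with fewer than 3 fields: %s",
                      paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  gene_set_library(sets, source = source)
}

#' @rdname read_gmt
#' @param library a `gene_set_library`.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library$sets), function(term) {
    paste(c(term, library$source, library$sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values (monotone, capped at 1), same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stopf("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a target set against a gene-set library
#'
#' Per term: the overlap of the targets with the term's genes (both
#' intersected with the background) is tested with the one-sided exact
#' hypergeometric upper tail; p-values are BH-adjusted across all terms. The
#' z-score is computed against a seeded random-set null: the overlap mean and
#' standard deviation over `n_null` uniform draws of `|targets|` genes from
#' the background. The combined score is `-ln(p) * z`, so larger means more
#' enriched; records are returned sorted by combined score descending.
#'
#' @param targets character vector of gene ids; must be a subset of the
#'   background.
#' @param library a [gene_set_library()].
#' @param background character vector of eligible gene ids; defaults to the
#'   union of the library's genes.
#' @param n_null number of random draws for the z-score null (default 1000).
#' @param null_seed RNG seed for the null draws (recorded in the result).
#' @return Data frame with columns `term`, `overlap_k`, `set_size_m`,
#'   `p_value`, `adjusted_p`, `odds_ratio`, `z_score`, `combined_score`.
#' @export
over_representation <- function(targets, library, background = NULL,
                                n_null = 1000L, null_seed = 1L) {
  stopifnot(inherits(library, "gene_set_library"))
  background <- sort_ids(unique(as.character(
    background %||% unlist(library$sets, use.names = FALSE))))
  targets <- sort_ids(unique(as.character(targets)))
  if (length(background) == 0L) stopf("background is empty")
  if (length(targets) == 0L) stopf("target set is empty")
  if (!all(targets %in% background))
    stopf("targets not in background: %s",
          paste(head(setdiff(targets, background), 5L), collapse = ", "))

  Nb <- length(background)
  nt <- length(targets)
  sets_bg <- lapply(library$sets, intersect, background)
  terms <- names(sets_bg)

  # one shared matrix of null draws, reused across terms
  null_draws <- withr::with_seed(null_seed, {
    replicate(n_null, sample(background, nt, replace = FALSE),
              simplify = FALSE)
  })

  rows <- lapply(terms, function(term) {
    genes <- sets_bg[[term]]
    m <- length(genes)
    k <- length(intersect(targets, genes))
    p <- if (m == 0L) 1 else hypergeometric_overlap(k, nt, m, Nb)
    null_k <- vapply(null_draws, function(d) sum(d %in% genes), numeric(1))
    mu <- mean(null_k)
    sigma <- sd(null_k)
    z <- if (is.na(sigma) || sigma == 0) 0 else (k - mu) / sigma
    a <- k; b <- nt - k; cc <- m - k; dd <- Nb - m - nt + k
    orat <- if (b * cc == 0) Inf else (a * dd) / (b * cc)
    data.frame(term = term, overlap_k = k, set_size_m = m, p_value = p,
               odds_ratio = orat, z_score = z,
               combined_score = -log(p) * z)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out <- out[order_by_score(out$combined_score, out$term), , drop = FALSE]
  out <- out[, c("term", "overlap_k", "set_size_m", "p_value", "adjusted_p",
                 "odds_ratio", "z_score", "combined_score")]
  rownames(out) <- NULL
  out
}

#' Drop disease-specific terms from an enrichment table
#'
#' Records whose term matches any of the exclusion patterns
#' (case-insensitive regular expressions) are removed; removed terms are
#' recorded in the `removed_terms` attribute.
#'
#' @param records data frame from [over_representation()].
#' @param exclusion_patterns character vector of patterns; empty -> identity.
#' @return Filtered records.
#' @export
filter_disease_terms <- function(records, exclusion_patterns = character()) {
  if (length(exclusion_patterns) == 0L) return(records)
  hit <- Reduce(`|`, lapply(exclusion_patterns, function(p) {
    grepl(p, records$term, ignore.case = TRUE)
  }))
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_terms") <- records$term[hit]
  out
}
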