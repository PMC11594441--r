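#' Construct a multiscale interactome
#'
#' A multiscale interactome is a two-class graph whose nodes are proteins and
#' biological functions, connected by three edge layers:
#' \describe{
#'   \item{ppi}{protein--protein physical interactions (undirected),}
#'   \item{annotation}{protein--function annotations (undirected),}
#'   \item{hierarchy}{function--function links, stored as (child, parent) and
#'     traversable both up and down.}
#' }
#' Node kinds are inferred from layer membership: ppi endpoints and annotation
#' first columns are proteins; hierarchy endpoints and annotation second
#' columns are functions. An id claimed by both classes is a validation error.
#'
#' Edges are canonicalized on construction: self-loops are dropped (counted in
#' the validation report), ppi pairs are stored with endpoints in radix-sorted
#' order, annotation pairs protein-first, and duplicate (source, target, layer)
#' triples are collapsed.
#'
#' @param ppi,annotation,hierarchy two-column data frames (or NULL) of edge
#'   endpoints. Hierarchy rows are read as (child, parent).
#' @param proteins,functions optional character vectors of extra node ids with
#'   no edges (permitted, flagged as isolated in the validation report).
#' @return An object of class `msnet` with elements `nodes` (data frame of
#'   `id`, `kind`) and `edges` (data frame of `from`, `to`, `layer`).
#' @seealso [load_network()], [summarize_network()], [write_network()]
#' @export
multiscale_network <- function(ppi = NULL, annotation = NULL, hierarchy = NULL,
                               proteins = character(), functions = character()) {
  as_pairs <- function(x, what) {
    if (is.null(x) || NROW(x) == 0L)
      return(data.frame(from = character(), to = character()))
    if (NCOL(x) < 2L) stopf("%s input needs at least two columns", what)
    data.frame(from = as.character(x[[1L]]), to = as.character(x[[2L]]))
  }
  ppi <- as_pairs(ppi, "ppi")
  annotation <- as_pairs(annotation, "annotation")
  hierarchy <- as_pairs(hierarchy, "hierarchy")

  n_self <- 0L
  drop_loops <- function(e) {
    keep <- e$from != e$to
    n_self <<- n_self + sum(!keep)
    e[keep, , drop = FALSE]
  }
  ppi <- drop_loops(ppi)
  annotation <- drop_loops(annotation)
  hierarchy <- drop_loops(hierarchy)

  prot_ids <- unique(c(ppi$from, ppi$to, annotation$from, as.character(proteins)))
  fun_ids <- unique(c(hierarchy$from, hierarchy$to, annotation$to,
                      as.character(functions)))
  clash <- intersect(prot_ids, fun_ids)
  if (length(clash) > 0L)
    stopf("id(s) declared as both protein and function: %s",
          paste(sort_ids(clash), collapse = ", "))

  # canonical orientations, then collapse duplicates
  ppi <- data.frame(from = pmin(ppi$from, ppi$to), to = pmax(ppi$from, ppi$to))
  n_dup <- 0L
  dedupe <- function(e) {
    if (nrow(e) == 0L) return(e)
    keep <- !duplicated(paste0(e$from, "\r", e$to))
    n_dup <<- n_dup + sum(!keep)
    e[keep, , drop = FALSE]
  }
  ppi <- dedupe(ppi)
  annotation <- dedupe(annotation)
  hierarchy <- dedupe(hierarchy)

  with_layer <- function(e, layer) {
    data.frame(from = e$from, to = e$to,
               layer = rep_len(layer, nrow(e)))
  }
  edges <- rbind(with_layer(ppi, "ppi"),
                 with_layer(annotation, "annotation"),
                 with_layer(hierarchy, "hierarchy"))
  rownames(edges) <- NULL

  nodes <- data.frame(
    id = c(sort_ids(prot_ids), sort_ids(fun_ids)),
    kind = c(rep("protein", length(prot_ids)), rep("function", length(fun_ids)))
  )

  net <- structure(
    list(nodes = nodes, edges = edges),
    class = "msnet",
    self_loops_dropped = n_self,
    duplicates_dropped = n_dup
  )
  net
}

#' Load a multiscale interactome from three edge-list files
#'
#' Each file is tab-separated with at least two columns (source id, target
#' id); `#`-prefixed lines are skipped and extra columns ignored. Hierarchy
#' rows are read as (child, parent); annotation rows as (protein, function).
#'
#' @param ppi_path,annotation_path,hierarchy_path paths to the three layers.
#' @return A validated [multiscale_network()].
#' @export
load_network <- function(ppi_path, annotation_path, hierarchy_path) {
  multiscale_network(
    ppi = read_edge_tsv(ppi_path),
    annotation = read_edge_tsv(annotation_path),
    hierarchy = read_edge_tsv(hierarchy_path)
  )
}

read_edge_tsv <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               quote = "", colClasses = "character", fill = TRUE),
    error = function(e) data.frame(V1 = character(), V2 = character())
  )
  if (nrow(tab) > 0L && ncol(tab) < 2L)
    stopf("edge list %s must have >= 2 tab-separated columns", path)
  tab
}

#' Write a network's canonicalized edge layers back to TSV
#'
#' Re-exports the stored (deduplicated, canonically oriented) edges; reading
#' the three files back with [load_network()] reproduces the edge multiset.
#'
#' @param net an `msnet`.
#' @param ppi_path,annotation_path,hierarchy_path output paths.
#' @return Invisibly, the paths.
#' @export
write_network <- function(net, ppi_path, annotation_path, hierarchy_path) {
  stopifnot(inherits(net, "msnet"))
  paths <- c(ppi = unname(ppi_path), annotation = unname(annotation_path),
             hierarchy = unname(hierarchy_path))
  for (layer in names(paths)) {
    e <- network_edges(net, layer)
    write.table(e[order(e$from, e$to, method = "radix"), c("from", "to")],
                paths[[layer]], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Summary counts for a multiscale interactome
#'
#' @param net an `msnet`.
#' @return One-row data frame with columns `proteins`, `functions`, `ppi`,
#'   `annotation`, `hierarchy`.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "msnet"))
  data.frame(
    proteins = sum(net$nodes$kind == "protein"),
    functions = sum(net$nodes$kind == "function"),
    ppi = sum(net$edges$layer == "ppi"),
    annotation = sum(net$edges$layer == "annotation"),
    hierarchy = sum(net$edges$layer == "hierarchy")
  )
}

#' Plain-text validation report for a network
#'
#' Reports counts of dropped self-loops and collapsed duplicate rows recorded
#' at construction, and flags isolated (zero-edge) nodes, which are legal but
#' unreachable by the walk.
#'
#' @param net an `msnet`.
#' @return Character vector of report lines.
#' @export
network_validation_report <- function(net) {
  stopifnot(inherits(net, "msnet"))
  touched <- unique(c(net$edges$from, net$edges$to))
  isolated <- setdiff(net$nodes$id, touched)
  c(
    sprintf("self loops dropped: %d", attr(net, "self_loops_dropped") %||% 0L),
    sprintf("duplicate rows collapsed: %d",
            attr(net, "duplicates_dropped") %||% 0L),
    sprintf("isolated nodes: %d%s", length(isolated),
            if (length(isolated) > 0L)
              paste0(" (", paste(sort_ids(isolated), collapse = ", "), ")")
            else "")
  )
}

#' @export
print.msnet <- function(x, ...) {
  s <- summarize_network(x)
  cat(sprintf(
    "multiscale interactome: %d proteins, %d functions; edges ppi=%d annotation=%d hierarchy=%d\n",
    s$proteins, s$functions, s$ppi, s$annotation, s$hierarchy))
  invisible(x)
}

#' Accessors for a multiscale interactome
#'
#' @param net an `msnet`.
#' @param layer optional layer name (`"ppi"`, `"annotation"`,
#'   `"hierarchy"`); NULL returns all edges.
#' @return Character vectors of node ids, or the edge data frame.
#' @export
network_node_ids <- function(net) net$nodes$id

#' @rdname network_node_ids
#' @export
network_proteins <- function(net) net$nodes$id[net$nodes$kind == "protein"]

#' @rdname network_node_ids
#' @export
network_functions <- function(net) net$nodes$id[net$nodes$kind == "function"]

#' @rdname network_node_ids
#' @export
network_edges <- function(net, layer = NULL) {
  if (is.null(layer)) return(net$edges)
  net$edges[net$edges$layer == layer, , drop = FALSE]
}
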