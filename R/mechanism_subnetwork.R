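#' Parameters for mechanism-subnetwork extraction
#'
#' @param k top entities taken from each diffusion profile (default 20; at
#'   k = 10 the top nodes of a profile already capture roughly half of the
#'   total visitation frequency, so 20 gives headroom).
#' @param include_direct_targets include the ingredient's direct protein
#'   targets even when outside the top-k sets (default TRUE).
#' @param association how "associated with the disease" is decided for the
#'   exclusion rule: `"reachability"` (path within the induced subgraph to a
#'   disease protein or disease-profile function; default, the weakest
#'   defensible reading) or `"adjacency"` (direct edge).
#' @return Object of class `subnetwork_parameters`.
#' @export
subnetwork_parameters <- function(k = 20L, include_direct_targets = TRUE,
                                  association = c("reachability", "adjacency")) {
  assert_count(k, "k", min = 1L)
  structure(list(k = as.integer(k),
                 include_direct_targets = isTRUE(include_direct_targets),
                 association = match.arg(association)),
            class = "subnetwork_parameters")
}

#' Top-k nodes of a diffusion profile
#'
#' @param profile a `diffusion_profile`.
#' @param k number of nodes; ties broken by node id ascending.
#' @param exclude node ids to skip (e.g. the seed entity's own pseudo-node).
#' @return Character vector of at most `k` node ids, highest frequency first.
#' @export
top_k_entities <- function(profile, k, exclude = character()) {
  stopifnot(inherits(profile, "diffusion_profile"))
  assert_count(k, "k", min = 1L)
  f <- profile$freq[!names(profile$freq) %in% exclude]
  ord <- order_by_score(f, names(f))
  names(f)[ord][seq_len(min(k, length(f)))]
}

#' Extract the mechanism subnetwork linking an ingredient to a disease
#'
#' Node set: the top-k nodes of the ingredient profile, the top-k nodes of
#' the disease profile, the ingredient's direct targets (optional), and the
#' disease proteins appearing in either top-k set. Ingredient targets not
#' associated with any disease protein or disease-profile function within the
#' induced subgraph are then removed. Edges are the parent-network edges
#' induced on the final node set, plus `targets` links from the ingredient
#' pseudo-node to its retained targets and `disease_link` edges from the
#' disease pseudo-node to its proteins in the set. The two pseudo-nodes do
#' not participate in the walk; they reproduce the ingredient--disease
#' topology of the exported mechanism figures.
#'
#' @param net an `msnet`.
#' @param ingredient_id id for the ingredient pseudo-node.
#' @param ingredient_target_ids the ingredient's direct protein targets.
#' @param disease a [disease_context()].
#' @param profile_ing,profile_dis diffusion profiles of the ingredient's
#'   targets and of the disease proteins, computed on `net`.
#' @param params a [subnetwork_parameters()].
#' @return Object of class `mechanism_subnetwork`: `nodes` (id, role, rank
#'   and frequency annotations per source profile) and `edges` (from, to,
#'   layer).
#' @export
build_subnetwork <- function(net, ingredient_id, ingredient_target_ids,
                             disease, profile_ing, profile_dis,
                             params = subnetwork_parameters()) {
  stopifnot(inherits(net, "msnet"), inherits(disease, "disease_context"))
  k <- params$k
  top_ing <- top_k_entities(profile_ing, k)
  top_dis <- top_k_entities(profile_dis, k)
  targets <- intersect(unique(as.character(ingredient_target_ids)),
                       network_node_ids(net))

  nodes <- union(top_ing, top_dis)
  if (params$include_direct_targets) nodes <- union(nodes, targets)
  dis_present <- intersect(disease$proteins, union(top_ing, top_dis))
  nodes <- union(nodes, dis_present)
  if (length(nodes) == 0L) stopf("empty mechanism subnetwork")

  e <- net$edges
  ind <- e[e$from %in% nodes & e$to %in% nodes, , drop = FALSE]

  # exclusion rule: drop ingredient targets with no association (path or
  # direct edge, per params$association) to a disease protein in the node
  # set or to a function selected by the disease profile
  anchors <- union(intersect(disease$proteins, nodes),
                   intersect(top_dis, network_functions(net)))
  if (length(targets) > 0L && length(anchors) > 0L) {
    g <- igraph::graph_from_data_frame(ind[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = data.frame(name = nodes))
    keep_target <- vapply(targets, function(tg) {
      if (tg %in% anchors) return(TRUE)
      if (params$association == "adjacency") {
        nb <- igraph::neighbors(g, tg)$name
        length(intersect(nb, anchors)) > 0L
      } else {
        d <- igraph::distances(g, v = tg, to = anchors)
        any(is.finite(d))
      }
    }, logical(1))
  } else {
    keep_target <- rep(length(anchors) > 0L, length(targets))
  }
  dropped <- targets[!keep_target]
  targets <- targets[keep_target]
  core <- union(union(top_ing, top_dis), dis_present)
  # excluded targets leave the subnetwork entirely, even if they also rank
  # in a top-k set
  nodes <- setdiff(sort_ids(union(intersect(nodes, core), targets)), dropped)
  if (length(nodes) == 0L) stopf("empty mechanism subnetwork after exclusion")
  ind <- e[e$from %in% nodes & e$to %in% nodes, , drop = FALSE]

  kind <- setNames(net$nodes$kind, net$nodes$id)
  rank_of <- function(profile) {
    ord <- order_by_score(profile$freq, names(profile$freq))
    setNames(seq_along(ord), names(profile$freq)[ord])
  }
  r_ing <- rank_of(profile_ing); r_dis <- rank_of(profile_dis)
  node_tab <- data.frame(
    id = nodes,
    role = unname(kind[nodes]),
    freq_ingredient = unname(profile_ing$freq[nodes]),
    freq_disease = unname(profile_dis$freq[nodes]),
    rank_ingredient = unname(r_ing[nodes]),
    rank_disease = unname(r_dis[nodes]),
    source = ifelse(nodes %in% top_ing & nodes %in% top_dis, "both",
                    ifelse(nodes %in% top_ing, "ingredient",
                           ifelse(nodes %in% top_dis, "disease", "target")))
  )
  node_tab <- rbind(
    data.frame(id = ingredient_id, role = "ingredient",
               freq_ingredient = NA_real_, freq_disease = NA_real_,
               rank_ingredient = NA_integer_, rank_disease = NA_integer_,
               source = "pseudo"),
    data.frame(id = disease$id, role = "disease",
               freq_ingredient = NA_real_, freq_disease = NA_real_,
               rank_ingredient = NA_integer_, rank_disease = NA_integer_,
               source = "pseudo"),
    node_tab
  )
  link_edges <- rbind(
    if (length(targets) > 0L)
      data.frame(from = ingredient_id, to = targets, layer = "targets"),
    if (length(intersect(disease$proteins, nodes)) > 0L)
      data.frame(from = disease$id,
                 to = intersect(disease$proteins, nodes),
                 layer = "disease_link")
  )
  edges <- rbind(ind, link_edges)
  edges <- edges[order(edges$layer, edges$from, edges$to, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- rownames(node_tab) <- NULL
  structure(list(nodes = node_tab, edges = edges,
                 ingredient = ingredient_id, disease = disease$id,
                 dropped_targets = sort_ids(dropped)),
            class = "mechanism_subnetwork")
}

#' @export
print.mechanism_subnetwork <- function(x, ...) {
  cat(sprintf("mechanism subnetwork %s -> %s: %d nodes, %d edges (%d target(s) excluded)\n",
              x$ingredient, x$disease, nrow(x$nodes), nrow(x$edges),
              length(x$dropped_targets)))
  invisible(x)
}

#' Export a mechanism subnetwork for external visualization
#'
#' SIF lines are `source<TAB>interaction<TAB>target` with the edge layer as
#' the interaction type; GraphML (via igraph) carries the node role and
#' profile-frequency annotations and round-trips node and edge sets through
#' [import_subnetwork()]. Output is deterministic: identical subnetworks
#' yield byte-identical SIF files.
#'
#' @param sub a `mechanism_subnetwork`.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_subnetwork <- function(sub, path, format = c("sif", "graphml")) {
  stopifnot(inherits(sub, "mechanism_subnetwork"))
  format <- match.arg(format)
  if (format == "sif") {
    writeLines(paste(sub$edges$from, sub$edges$layer, sub$edges$to,
                     sep = "\t"), path)
  } else {
    g <- subnetwork_igraph(sub)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

subnetwork_igraph <- function(sub) {
  v <- sub$nodes
  v$freq_ingredient[is.na(v$freq_ingredient)] <- -1
  v$freq_disease[is.na(v$freq_disease)] <- -1
  igraph::graph_from_data_frame(sub$edges, directed = FALSE, vertices = v)
}

#' Re-import an exported subnetwork's node and edge sets
#'
#' @param path file written by [export_subnetwork()].
#' @param format `"sif"` or `"graphml"`.
#' @return List with `nodes` (ids; with role/frequency attributes for
#'   GraphML) and `edges` (from, to, layer).
#' @export
import_subnetwork <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    parts <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[[`, character(1), 1L),
                        layer = vapply(parts, `[[`, character(1), 2L),
                        to = vapply(parts, `[[`, character(1), 3L))
    list(nodes = sort_ids(unique(c(edges$from, edges$to))),
         edges = edges[, c("from", "to", "layer")])
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    nd <- igraph::as_data_frame(g, what = "vertices")
    list(nodes = nd, edges = data.frame(from = ed$from, to = ed$to,
                                        layer = ed$layer))
  }
}

#' Node annotation table of a subnetwork
#'
#' @param sub a `mechanism_subnetwork`.
#' @return Data frame (node, role, frequencies, ranks, source profile).
#' @export
subnetwork_annotation <- function(sub) {
  stopifnot(inherits(sub, "mechanism_subnetwork"))
  sub$nodes
}
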