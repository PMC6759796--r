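#' Consensus hub targets: topology intersect clustering
#'
#' The hub-calling rule combines the two independent analyses: a symbol
#' is a consensus hub iff it passes the topological (mean-degree) filter
#' *and* belongs to the top dense cluster. Cluster member lists may mix
#' compound and target nodes; comparison happens on normalized symbols,
#' so compound ids simply never match.
#'
#' @param topological_hubs character vector (or [target_set]) of hub
#'   target symbols from the topological analysis.
#' @param cluster_members character vector of cluster node labels.
#' @return sorted character vector of consensus hub symbols.
#' @export
intersect_hubs <- function(topological_hubs, cluster_members) {
  hubs <- as_target_set(topological_hubs)$symbols
  if (length(cluster_members) == 0L) return(character())
  sort(intersect(hubs, normalize_symbol(cluster_members)))
}

#' Filter scored PPI edges at a confidence cutoff
#'
#' Retains edges whose association score is at least `min_score`
#' (inclusive, so the conventional "highest confidence" cutoff keeps a
#' score of exactly 0.9). Row order is preserved.
#'
#' @param edges data frame with columns `node1`, `node2`, `score`.
#' @param min_score cutoff in \[0, 1\], default 0.9.
#' @return the retained rows.
#' @export
filter_ppi_edges <- function(edges, min_score = 0.9) {
  stopifnot(min_score >= 0, min_score <= 1)
  out <- edges[edges$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the PPI network and classify its nodes
#'
#' Builds the simple undirected graph over the endpoints of a (filtered)
#' scored edge table, carrying scores as edge attributes, and classifies
#' each node as a `hub` (member of the consensus hub set) or a
#' `predicted` functional partner (everything else). The same unordered
#' pair listed twice with conflicting scores is an error; a repeat with
#' the same score collapses silently.
#'
#' @param edges data frame with columns `node1`, `node2`, `score`.
#' @param hubs character vector of consensus hub symbols (may be empty;
#'   hubs absent from the edge table are simply not in the graph).
#' @return igraph with vertex attribute `role` in `{"hub", "predicted"}`
#'   and edge attribute `score`.
#' @export
build_ppi_network <- function(edges, hubs = character()) {
  n1 <- normalize_symbol(as.character(edges$node1))
  n2 <- normalize_symbol(as.character(edges$node2))
  if (any(n1 == n2)) stop("self-interaction in PPI edge table", call. = FALSE)
  key <- paste(pmin(n1, n2), pmax(n1, n2))
  by_pair <- split(edges$score, key)
  conflict <- vapply(by_pair, function(s) length(unique(s)) > 1L, TRUE)
  if (any(conflict))
    stop("conflicting scores for pair(s): ",
         paste(names(by_pair)[conflict], collapse = ", "), call. = FALSE)
  first <- !duplicated(key)
  hubs <- if (length(hubs)) normalize_symbol(hubs) else character()
  nodes <- sort(unique(c(n1, n2)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = n1[first], to = n2[first], score = edges$score[first],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes,
                          role = ifelse(nodes %in% hubs, "hub", "predicted"),
                          stringsAsFactors = FALSE))
  g
}

#' Hub report
#'
#' Summarizes the hub-calling stage: the topological hub set, the top
#' cluster's target members, their intersection (the consensus hubs) and
#' the predicted functional partners appearing in a PPI node set but not
#' in the consensus.
#'
#' @param topological_hubs character vector of hub symbols from topology.
#' @param cluster_members character vector of top-cluster node labels.
#' @param ppi_nodes character vector of PPI network node symbols
#'   (optional; enables the predicted-functional set).
#' @param target_nodes optional character vector of known target symbols;
#'   when given, `cluster_targets` is restricted to it (dropping compound
#'   nodes from mixed cluster memberships).
#' @return list with `topological_hubs`, `cluster_targets`, `consensus`,
#'   `predicted_functional`.
#' @export
hub_report <- function(topological_hubs, cluster_members, ppi_nodes = character(),
                       target_nodes = NULL) {
  consensus <- intersect_hubs(topological_hubs, cluster_members)
  ppi_nodes <- if (length(ppi_nodes)) normalize_symbol(ppi_nodes) else character()
  cluster_targets <- if (length(cluster_members))
    sort(unique(normalize_symbol(cluster_members))) else character()
  if (!is.null(target_nodes))
    cluster_targets <- intersect(cluster_targets, normalize_symbol(target_nodes))
  list(topological_hubs = sort(as_target_set(topological_hubs)$symbols),
       cluster_targets = cluster_targets,
       consensus = consensus,
       predicted_functional = sort(setdiff(ppi_nodes, consensus)))
}
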