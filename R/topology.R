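#' Connected components of an undirected graph
#'
#' @param graph igraph object.
#' @return list of character vectors of node names, one per component,
#'   ordered by decreasing size (ties by first node name).
#' @export
connected_components <- function(graph) {
  comp <- igraph::components(graph)
  members <- split(igraph::V(graph)$name, comp$membership)
  members <- lapply(members, sort)
  ord <- order(-lengths(members),
               vapply(members, `[`, "", 1L))
  unname(members[ord])
}

#' Per-node topological metrics (NetworkAnalyzer convention)
#'
#' Computes, for every node of a simple undirected graph, the four
#' metrics used to rank hub candidates: degree, normalized betweenness
#' centrality, average shortest path length, and closeness centrality.
#' All path-based metrics are computed *within the node's connected
#' component*: the average shortest path length is the mean BFS distance
#' to the other members of the component, closeness is its reciprocal,
#' and betweenness is the fraction of pairwise shortest paths through the
#' node, normalized by `(n-1)(n-2)/2` with `n` the component size. An
#' isolated node gets an undefined (NA) path length, closeness 0 and
#' betweenness 0. Multi-edges and self-loops are collapsed before
#' computation.
#'
#' @param graph igraph object (undirected).
#' @return data frame with columns `node`, `degree`, `betweenness`,
#'   `avg_shortest_path`, `closeness`, one row per node, sorted with
#'   [rank_nodes()] order (degree desc, betweenness desc, node asc).
#' @export
node_topology <- function(graph) {
  g <- igraph::simplify(igraph::as_undirected(graph))
  n <- igraph::vcount(g)
  if (n == 0L)
    return(data.frame(node = character(), degree = integer(),
                      betweenness = numeric(), avg_shortest_path = numeric(),
                      closeness = numeric(), stringsAsFactors = FALSE))
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  deg <- igraph::degree(g)
  btw_raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  comp <- igraph::components(g)
  csize <- comp$csize[comp$membership]
  # per-component pair normalization; components of size <= 2 carry no
  # intermediate paths
  denom <- (csize - 1) * (csize - 2) / 2
  btw <- ifelse(denom > 0, btw_raw / denom, 0)
  d <- igraph::distances(g)
  aspl <- vapply(seq_len(n), function(i) {
    same <- which(comp$membership == comp$membership[i])
    same <- setdiff(same, i)
    if (length(same) == 0L) return(NA_real_)
    mean(d[i, same])
  }, 0)
  clo <- ifelse(is.na(aspl), 0, 1 / aspl)
  out <- data.frame(node = nodes, degree = as.integer(deg), betweenness = btw,
                    avg_shortest_path = aspl, closeness = clo,
                    stringsAsFactors = FALSE, row.names = NULL)
  rank_nodes(out)
}

#' Order a topology table for hub reporting
#'
#' Stable sort by degree (descending), then betweenness (descending),
#' then node id (ascending) as the deterministic tie-break.
#'
#' @param topology data frame with columns `node`, `degree`,
#'   `betweenness`.
#' @return the reordered data frame.
#' @export
rank_nodes <- function(topology) {
  if (nrow(topology) == 0L) return(topology)
  ord <- order(-topology$degree, -topology$betweenness, topology$node)
  out <- topology[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the major hub subnetwork by the mean-degree threshold
#'
#' The hub rule keeps nodes whose degree is *strictly greater* than the
#' network's average number of neighbors (the mean distinct-neighbor
#' count over all nodes) and induces the subgraph on them. The computed
#' threshold is returned alongside so reports can state it.
#'
#' @param graph igraph object (nonempty).
#' @return list with elements `subgraph` (igraph), `threshold` (the mean
#'   neighbor count) and `nodes` (retained node names).
#' @export
extract_major_hub_network <- function(graph) {
  g <- igraph::simplify(igraph::as_undirected(graph))
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  deg <- igraph::degree(g)
  thr <- mean(deg)
  keep <- names(deg)[deg > thr]
  list(subgraph = igraph::induced_subgraph(g, keep),
       threshold = thr,
       nodes = sort(keep))
}

#' Write a topology table as TSV
#'
#' Column layout mirrors the NetworkAnalyzer export used in hub reports
#' ("Genes/proteins, Degree, Betweenness centrality, Average shortest
#' path length, Closeness centrality"); floats are printed to 8 decimals.
#'
#' @param topology data frame from [node_topology()].
#' @param path file path.
#' @export
write_topology_tsv <- function(topology, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 8, format = "f"))
  out <- data.frame(`Genes/proteins` = topology$node,
                    Degree = topology$degree,
                    `Betweenness centrality` = fmt(topology$betweenness),
                    `Average shortest path length` = fmt(topology$avg_shortest_path),
                    `Closeness centrality` = fmt(topology$closeness),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
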