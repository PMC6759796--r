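#' Build the bipartite component-target (C-T) network
#'
#' One node per compound and per consensus target, and an undirected edge
#' (compound, target) whenever at least one source database asserts the
#' pair and the target belongs to the consensus set. Assertions duplicated
#' across databases collapse to a single edge; compounds left without any
#' consensus target are dropped from the network.
#'
#' @param ct_map data frame with columns `compound_id`, `target_symbol`
#'   (and optionally `source_tag`).
#' @param consensus a [target_set] (or character vector) of consensus
#'   target symbols; must be a subset of the map's target union.
#' @return an igraph object with vertex attributes `name` and `part`
#'   (`"compound"` or `"target"`).
#' @export
build_ct_network <- function(ct_map, consensus) {
  consensus <- as_target_set(consensus)
  if (length(consensus$symbols) == 0L) {
    warning("empty consensus set: returning an empty network")
    return(igraph::make_empty_graph(directed = FALSE))
  }
  sym <- normalize_symbol(ct_map$target_symbol)
  if (!all(consensus$symbols %in% sym))
    stop("consensus set is not a subset of the mapped targets", call. = FALSE)
  keep <- sym %in% consensus$symbols
  pairs <- unique(data.frame(compound = as.character(ct_map$compound_id[keep]),
                             target = sym[keep], stringsAsFactors = FALSE))
  compounds <- sort(unique(pairs$compound))
  targets <- sort(unique(pairs$target))
  g <- igraph::graph_from_data_frame(
    pairs,
    directed = FALSE,
    vertices = data.frame(name = c(compounds, targets),
                          part = rep(c("compound", "target"),
                                     c(length(compounds), length(targets))),
                          stringsAsFactors = FALSE))
  igraph::simplify(g)
}

#' Target-part node names of a C-T (or classified) network
#'
#' @param graph igraph with a `part` vertex attribute.
#' @param part which part to extract.
#' @return character vector of node names.
#' @export
network_part <- function(graph, part = c("target", "compound")) {
  part <- match.arg(part)
  if (!"part" %in% igraph::vertex_attr_names(graph))
    stop("graph has no 'part' vertex attribute", call. = FALSE)
  igraph::V(graph)$name[igraph::V(graph)$part == part]
}

#' Bundled high-confidence PPI edge fixture
#'
#' A curated 28-interaction STRING-style edge list over 16 heart-failure
#' related proteins (six hub targets and ten predicted functional
#' partners), every score at or above the 0.9 highest-confidence cutoff.
#' Used as a small, fully in-package input for the PPI and topology
#' stages.
#'
#' @return data frame with columns `node1`, `node2`, `score` (28 rows).
#' @export
load_fixture_ppi <- function() {
  read_edge_tsv(system.file("extdata", "hub_ppi.tsv", package = "netpharm",
                            mustWork = TRUE))
}

#' Bundled major-target topology table fixture
#'
#' The 32 major putative targets that pass the mean-neighbor degree
#' threshold in the bundled study network, with their four topological
#' metrics.
#'
#' @return data frame with columns `uniprot`, `gene`, `degree`,
#'   `betweenness`, `avg_shortest_path`, `closeness`.
#' @export
load_fixture_major_targets <- function() {
  read.delim(system.file("extdata", "major_targets.tsv", package = "netpharm",
                         mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Bundled top dense-cluster membership fixture
#'
#' The 17 members (targets and compound nodes) of the highest-scoring
#' MCODE cluster of the bundled study network.
#'
#' @return character vector of 17 node labels.
#' @export
load_fixture_top_cluster <- function() {
  read_target_list(system.file("extdata", "top_cluster_nodes.txt",
                               package = "netpharm", mustWork = TRUE))
}
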