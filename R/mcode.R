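#' MCODE parameter set
#'
#' Parameters of the Molecular Complex Detection algorithm, defaulting to
#' the published plugin defaults: degree cutoff 2, node score cutoff 0.2,
#' k-core threshold 2, max depth 100, haircut on, fluff off with fluff
#' density 0.1.
#'
#' @param degree_cutoff minimum degree for a node to receive a nonzero
#'   weight seedable in clustering.
#' @param node_score_cutoff fraction in \[0,1\]: a neighbor joins a
#'   cluster if its weight is at least `(1 - node_score_cutoff)` times the
#'   seed weight.
#' @param k_core_threshold clusters lacking a k-core at this k are
#'   discarded in post-processing.
#' @param max_depth maximum BFS depth of cluster expansion from the seed.
#' @param haircut if TRUE, iteratively shave cluster members with fewer
#'   than 2 connections inside the cluster.
#' @param fluff if TRUE, add boundary neighbors whose closed-neighborhood
#'   density exceeds `fluff_density`.
#' @param fluff_density density threshold for fluffing.
#' @return list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core_threshold = 2, max_depth = 100,
                         haircut = TRUE, fluff = FALSE, fluff_density = 0.1) {
  stopifnot(degree_cutoff >= 0, k_core_threshold >= 0, max_depth >= 0,
            node_score_cutoff >= 0, node_score_cutoff <= 1,
            fluff_density >= 0, fluff_density <= 1)
  structure(list(degree_cutoff = degree_cutoff,
                 node_score_cutoff = node_score_cutoff,
                 k_core_threshold = k_core_threshold,
                 max_depth = max_depth, haircut = haircut, fluff = fluff,
                 fluff_density = fluff_density),
            class = "mcode_params")
}

#' k-core of a graph
#'
#' The maximal subgraph in which every node has at least `k` neighbors
#' within the subgraph, obtained by iteratively pruning nodes of degree
#' below `k` until a fixpoint.
#'
#' @param graph igraph object.
#' @param k nonnegative integer.
#' @return igraph subgraph (possibly empty).
#' @export
k_core <- function(graph, k) {
  stopifnot(k >= 0)
  g <- igraph::simplify(igraph::as_undirected(graph))
  repeat {
    deg <- igraph::degree(g)
    drop <- deg < k
    if (!any(drop) || igraph::vcount(g) == 0L) break
    g <- igraph::delete_vertices(g, igraph::V(g)[drop])
  }
  g
}

# highest-k core of a graph: returns list(k, core). Empty graph -> k = 0.
highest_k_core <- function(graph) {
  k <- 0L
  core <- graph
  repeat {
    cand <- k_core(graph, k + 1L)
    if (igraph::vcount(cand) == 0L) break
    k <- k + 1L
    core <- cand
  }
  list(k = k, core = core)
}

graph_density <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2L) return(0)
  2 * igraph::ecount(graph) / (n * (n - 1))
}

#' MCODE vertex weight
#'
#' The weight of a node is `k * density` of the highest-k core of the
#' subgraph induced by the node's closed neighborhood (the node plus its
#' neighbors), with density `2E / (n (n - 1))`. High weights mark nodes
#' embedded in locally dense regions; a node inside a clique K_m scores
#' `m - 1`. Isolated nodes weigh 0.
#'
#' @param graph igraph object.
#' @param nodes node names (default: all); absent nodes are an error.
#' @return named numeric vector of weights.
#' @export
vertex_weight <- function(graph, nodes = igraph::V(graph)$name) {
  g <- igraph::simplify(igraph::as_undirected(graph))
  all_names <- igraph::V(g)$name
  if (!all(nodes %in% all_names))
    stop("node(s) not in graph: ",
         paste(setdiff(nodes, all_names), collapse = ", "), call. = FALSE)
  adj <- igraph::adjacent_vertices(g, nodes)
  w <- vapply(seq_along(nodes), function(i) {
    nb <- adj[[i]]$name
    if (length(nb) == 0L) return(0)
    h <- igraph::induced_subgraph(g, c(nodes[i], nb))
    hk <- highest_k_core(h)
    hk$k * graph_density(hk$core)
  }, 0)
  setNames(w, nodes)
}

#' MCODE cluster prediction
#'
#' Seeds are chosen in decreasing vertex weight among nodes not yet
#' assigned to a cluster (ties broken lexicographically by node id);
#' each cluster grows breadth-first from its seed, admitting a neighbor
#' iff the neighbor is unassigned, its weight is at least
#' `seed_weight * (1 - node_score_cutoff)`, and its BFS depth does not
#' exceed `max_depth`. A node failing the weight threshold blocks
#' traversal through it. Nodes below `degree_cutoff` never seed. Each
#' node belongs to at most one cluster; clusters are returned ordered by
#' score (density times size) descending.
#'
#' @param graph igraph object.
#' @param params an [mcode_params()] list.
#' @return list of clusters, each a list with `seed`, `members`
#'   (character), `score`, `size`.
#' @export
predict_clusters <- function(graph, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  g <- igraph::simplify(igraph::as_undirected(graph))
  if (igraph::vcount(g) == 0L) return(list())
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  nodes <- igraph::V(g)$name
  w <- vertex_weight(g)
  deg <- igraph::degree(g)
  assigned <- setNames(rep(FALSE, length(nodes)), nodes)
  neighbors_of <- lapply(igraph::adjacent_vertices(g, nodes), function(v) v$name)
  names(neighbors_of) <- nodes
  # seed order: weight desc, name asc; zero-weight or low-degree nodes
  # cannot seed
  seed_order <- nodes[order(-w, nodes)]
  seed_order <- seed_order[w[seed_order] > 0 & deg[seed_order] >= params$degree_cutoff]
  clusters <- list()
  for (seed in seed_order) {
    if (assigned[seed]) next
    thr <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      nxt <- character()
      for (v in frontier) {
        for (u in neighbors_of[[v]]) {
          if (!assigned[u] && w[u] >= thr) {
            assigned[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(g, members)
    clusters[[length(clusters) + 1L]] <-
      list(seed = seed, members = sort(members),
           score = graph_density(sub) * length(members),
           size = length(members))
  }
  order_clusters(clusters)
}

order_clusters <- function(clusters) {
  if (length(clusters) == 0L) return(clusters)
  ord <- order(-vapply(clusters, `[[`, 0, "score"),
               vapply(clusters, `[[`, "", "seed"))
  clusters[ord]
}

#' MCODE post-processing
#'
#' Discards clusters lacking a k-core at `k_core_threshold` (unless fluff
#' is on), optionally shaves singly-connected members ("haircut",
#' iterated to a fixpoint, i.e. the cluster's 2-core), and optionally
#' "fluffs" the cluster with boundary neighbors whose closed-neighborhood
#' density exceeds `fluff_density`. Scores and sizes are recomputed.
#'
#' @param clusters list from [predict_clusters()].
#' @param graph the graph they came from.
#' @param params an [mcode_params()] list.
#' @return filtered/trimmed cluster list, reordered by score.
#' @export
postprocess_clusters <- function(clusters, graph, params = mcode_params()) {
  g <- igraph::simplify(igraph::as_undirected(graph))
  out <- list()
  for (cl in clusters) {
    sub <- igraph::induced_subgraph(g, cl$members)
    if (!params$fluff &&
        igraph::vcount(k_core(sub, params$k_core_threshold)) == 0L)
      next
    members <- cl$members
    if (params$haircut) {
      trimmed <- k_core(igraph::induced_subgraph(g, members), 2)
      members <- sort(igraph::V(trimmed)$name)
      if (length(members) == 0L) next
    }
    if (params$fluff) {
      boundary <- setdiff(
        unique(unlist(lapply(igraph::adjacent_vertices(g, members),
                             function(v) v$name))),
        members)
      dens <- vapply(boundary, function(u) {
        nb <- igraph::adjacent_vertices(g, u)[[1]]$name
        graph_density(igraph::induced_subgraph(g, c(u, nb)))
      }, 0)
      members <- sort(c(members, boundary[dens > params$fluff_density]))
    }
    sub <- igraph::induced_subgraph(g, members)
    if (!cl$seed %in% members) cl$seed <- members[1L]
    out[[length(out) + 1L]] <- list(seed = cl$seed, members = members,
                                    score = graph_density(sub) * length(members),
                                    size = length(members))
  }
  order_clusters(out)
}

#' Run the full MCODE procedure
#'
#' Vertex weighting, cluster prediction and post-processing in one call.
#'
#' @inheritParams predict_clusters
#' @return ordered cluster list (see [predict_clusters()]).
#' @export
mcode <- function(graph, params = mcode_params()) {
  postprocess_clusters(predict_clusters(graph, params), graph, params)
}

#' Write clusters as TSV
#'
#' One row per cluster: rank, score, size, seed, comma-joined members.
#'
#' @param clusters cluster list.
#' @param path file path.
#' @export
write_clusters_tsv <- function(clusters, path) {
  out <- data.frame(
    rank = seq_along(clusters),
    score = vapply(clusters, `[[`, 0, "score"),
    size = vapply(clusters, `[[`, 0L, "size"),
    seed = vapply(clusters, `[[`, "", "seed"),
    members = vapply(clusters, function(cl) paste(cl$members, collapse = ","), ""),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
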