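# Independent brute-force oracles for the graph metrics, written against
# adjacency matrices with naive enumeration so they share no code path
# with the package implementations. Only viable for tiny graphs.

# all simple paths from s to t as vectors of vertex indices
enumerate_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (u in seq_len(n)) {
      if (adj[v, u] == 1 && !(u %in% path)) walk(c(path, u))
    }
  }
  walk(s)
  paths
}

# normalized betweenness + avg shortest path + closeness by exhaustive
# shortest-path enumeration, per connected component
oracle_topology <- function(adj) {
  n <- nrow(adj)
  # component labels by repeated matrix closure
  reach <- (adj + diag(n)) > 0
  for (i in seq_len(n)) reach <- (reach %*% reach) > 0
  comp <- match(apply(reach, 1, paste, collapse = ""),
                unique(apply(reach, 1, paste, collapse = "")))
  btw <- numeric(n)
  aspl <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    others <- setdiff(which(comp == comp[v]), v)
    if (length(others) == 0L) next
    dists <- numeric(length(others))
    for (j in seq_along(others)) {
      paths <- enumerate_paths(adj, v, others[j])
      dists[j] <- min(lengths(paths)) - 1L
    }
    aspl[v] <- mean(dists)
  }
  for (v in seq_len(n)) {
    members <- which(comp == comp[v])
    nc <- length(members)
    if (nc < 3L) next
    frac <- 0
    prs <- t(utils::combn(setdiff(members, v), 2L))
    for (r in seq_len(nrow(prs))) {
      paths <- enumerate_paths(adj, prs[r, 1], prs[r, 2])
      len <- lengths(paths)
      shortest <- paths[len == min(len)]
      frac <- frac + mean(vapply(shortest, function(p) v %in% p[-c(1, length(p))],
                                 TRUE))
    }
    btw[v] <- frac / ((nc - 1) * (nc - 2) / 2)
  }
  data.frame(degree = rowSums(adj), betweenness = btw,
             avg_shortest_path = aspl,
             closeness = ifelse(is.na(aspl), 0, 1 / aspl))
}

# k-core by exhaustive subset search: union of all vertex subsets whose
# induced subgraph has minimum degree >= k
oracle_k_core_members <- function(adj, k) {
  n <- nrow(adj)
  members <- logical(n)
  for (code in seq_len(2^n) - 1L) {
    sub <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
    if (length(sub) == 0L) next
    degs <- rowSums(adj[sub, sub, drop = FALSE])
    if (all(degs >= k)) members[sub] <- TRUE
  }
  which(members)
}

adj_of <- function(g) {
  m <- as.matrix(igraph::as_adjacency_matrix(g))
  rownames(m) <- colnames(m) <- igraph::V(g)$name
  m
}

named_graph <- function(edges_chr, isolated = character()) {
  # edges_chr: character vector like c("a-b", "b-c")
  el <- do.call(rbind, strsplit(edges_chr, "-", fixed = TRUE))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}

random_named_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# sparse random background with a planted 5-clique bridged into it
planted_k5_graph <- function(seed, n_background = 30, p = 0.05) {
  set.seed(seed)
  g <- igraph::sample_gnp(n_background, p)
  igraph::V(g)$name <- sprintf("b%02d", seq_len(n_background))
  clique_nodes <- sprintf("k%d", 1:5)
  g <- igraph::add_vertices(g, 5, name = clique_nodes)
  pairs <- t(utils::combn(clique_nodes, 2))
  g <- igraph::add_edges(g, c(t(pairs)))
  # a couple of bridges so the clique is not a separate component
  g <- igraph::add_edges(g, c("k1", "b01", "k3", "b02"))
  list(graph = igraph::simplify(g), clique = clique_nodes)
}

# small graph zoo for the metric-equivalence suites
graph_classes_upto <- function(nmax) {
  zoo <- list()
  for (n in 2:nmax) {
    zoo[[paste0("path", n)]] <- igraph::make_ring(n, circular = FALSE)
    if (n >= 3) zoo[[paste0("cycle", n)]] <- igraph::make_ring(n, circular = TRUE)
    zoo[[paste0("star", n)]] <- igraph::make_star(n, mode = "undirected")
    zoo[[paste0("full", n)]] <- igraph::make_full_graph(n)
  }
  zoo[["tree7"]] <- igraph::make_tree(7, children = 2, mode = "undirected")
  zoo[["bipartite23"]] <- igraph::make_full_bipartite_graph(2, 3)
  zoo[["bipartite34"]] <- igraph::make_full_bipartite_graph(3, 4)
  lapply(zoo, function(g) {
    igraph::V(g)$name <- sprintf("n%02d", seq_len(igraph::vcount(g)))
    g
  })
}
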