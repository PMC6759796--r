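test_that("connected components partition the fixture graph into 11/3/2", {
  g <- build_ppi_network(load_fixture_ppi())
  comps <- connected_components(g)
  expect_equal(lengths(comps), c(11L, 3L, 2L))
  expect_setequal(unlist(comps), igraph::V(g)$name)
  # edgeless graph: all singletons; complete graph: one component
  iso <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(iso)$name <- letters[1:4]
  expect_equal(lengths(connected_components(iso)), rep(1L, 4))
  expect_equal(lengths(connected_components(graph_classes_upto(5)$full5)), 5L)
})

test_that("symmetric graphs have the expected closed-form metrics", {
  k3 <- graph_classes_upto(3)$full3
  topo <- node_topology(k3)
  expect_equal(topo$betweenness, rep(0, 3))
  expect_equal(topo$closeness, rep(1, 3))
  # path a-b-c-d: inner node carries 2 of its 3 foreign pairs
  p4 <- named_graph(c("a-b", "b-c", "c-d"))
  t4 <- node_topology(p4)
  expect_equal(t4$betweenness[t4$node == "b"], 2 / 3)
  expect_equal(t4$avg_shortest_path[t4$node == "b"], (1 + 1 + 2) / 3)
})

test_that("isolated nodes get closeness 0, betweenness 0, undefined path length", {
  g <- named_graph("a-b", isolated = "z")
  topo <- node_topology(g)
  z <- topo[topo$node == "z", ]
  expect_equal(z$closeness, 0)
  expect_equal(z$betweenness, 0)
  expect_true(is.na(z$avg_shortest_path))
})

test_that("metrics agree with brute-force path enumeration across small graph classes", {
  zoo <- graph_classes_upto(6)
  for (seed in 1:8) {
    n <- sample(4:8, 1)
    zoo[[paste0("rnd", seed)]] <- random_named_gnp(n, runif(1, 0.2, 0.7),
                                                   seed = 100 + seed)
  }
  for (nm in names(zoo)) {
    g <- zoo[[nm]]
    got <- node_topology(g)
    got <- got[order(got$node), ]
    adj <- adj_of(g)
    want <- oracle_topology(adj)[order(rownames(adj)), ]
    expect_equal(got$degree, unname(want$degree), info = nm)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12, info = nm)
    expect_equal(got$avg_shortest_path, want$avg_shortest_path,
                 tolerance = 1e-12, info = nm)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-12, info = nm)
  }
})

test_that("closeness is the reciprocal of the average path length for every non-isolated node", {
  for (seed in 1:6) {
    g <- random_named_gnp(10, 0.3, seed = 200 + seed)
    topo <- node_topology(g)
    ok <- !is.na(topo$avg_shortest_path)
    expect_equal(topo$closeness[ok] * topo$avg_shortest_path[ok],
                 rep(1, sum(ok)))
    expect_equal(topo$closeness[!ok], rep(0, sum(!ok)))
    # degree sum identity
    expect_equal(sum(topo$degree), 2 * igraph::ecount(igraph::simplify(g)))
  }
})

test_that("hub extraction applies a strict mean-degree threshold", {
  # k-regular graph: nobody is strictly above the mean
  ring <- graph_classes_upto(6)$cycle6
  expect_equal(igraph::vcount(extract_major_hub_network(ring)$subgraph), 0)
  # star with 5 leaves: only the center survives the mean of 10/6
  star <- graph_classes_upto(6)$star6
  hub <- extract_major_hub_network(star)
  expect_equal(hub$threshold, 10 / 6)
  expect_equal(hub$nodes, "n01")
  expect_error(extract_major_hub_network(igraph::make_empty_graph(directed = FALSE)),
               "empty")
})

test_that("node ranking sorts by degree then betweenness with stable id tie-break", {
  topo <- node_topology(build_ppi_network(load_fixture_ppi()))
  ranked <- rank_nodes(topo)
  expect_equal(ranked$node[1:2], c("VEGFA", "STAT3")) # degree tie, betweenness splits
  # oracle comparison sort on random tables
  set.seed(31)
  tab <- data.frame(node = sample(sprintf("g%02d", 1:20)),
                    degree = sample(1:5, 20, replace = TRUE),
                    betweenness = round(runif(20), 2))
  got <- rank_nodes(tab)
  key <- function(d) order(-d$degree, -d$betweenness, d$node)
  expect_equal(got$node, tab$node[key(tab)])
})

test_that("multi-edges are collapsed before metric computation", {
  g <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("a", "b"), c("b", "c")),
                                   directed = FALSE)
  topo <- node_topology(g)
  expect_equal(topo$degree[topo$node == "a"], 1L)
  expect_equal(sum(topo$degree), 4L)
})

test_that("topology TSV prints 8-decimal metrics under the report header", {
  topo <- node_topology(build_ppi_network(load_fixture_ppi()))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_topology_tsv(topo, path)
  lines <- readLines(path)
  expect_match(lines[1], "^Genes/proteins\tDegree\tBetweenness centrality")
  vegfa <- strsplit(grep("^VEGFA", lines, value = TRUE), "\t")[[1]]
  expect_equal(vegfa, c("VEGFA", "7", "0.47407407", "1.30000000", "0.76923077"))
})
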