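#!/usr/bin/env Rscript
# Stage 5: confidence-filtered PPI subnetwork and its topology table.
#
# Runs the PPI stage twice: on the bundled 28-edge high-confidence
# fixture (whose topology table is fully known and acts as the exact
# regression surface), and on the simulated scored edges filtered at the
# 0.9 highest-confidence cutoff.

library(netpharm)

# bundled fixture: 16 proteins, 28 interactions, all scores >= 0.9
edges <- load_fixture_ppi()
hubs9 <- intersect_hubs(load_fixture_major_targets()$gene,
                        load_fixture_top_cluster())
ppi <- build_ppi_network(filter_ppi_edges(edges, 0.9), hubs9)
write_sif(ppi, "results/fixture_ppi.sif")
topo <- node_topology(ppi)
write_topology_tsv(topo, "results/fixture_ppi_topology.tsv")
roles <- igraph::V(ppi)$role
cat(sprintf("fixture PPI: %d nodes (%d hubs + %d predicted), %d edges, %d components\n",
            igraph::vcount(ppi), sum(roles == "hub"), sum(roles == "predicted"),
            igraph::ecount(ppi), length(connected_components(ppi))))
cat("highest-degree rows:\n")
print(utils::head(topo, 3), digits = 8)

# simulated edges at the same cutoff
sim <- read_edge_tsv("results/data/ppi_edges.tsv")
kept <- filter_ppi_edges(sim, 0.9)
sim_net <- build_ppi_network(kept, read_target_list("results/consensus_hubs.txt"))
write_topology_tsv(node_topology(sim_net), "results/sim_ppi_topology.tsv")
cat(sprintf("simulated PPI: %d of %d edges survive the 0.9 cutoff (%d nodes)\n",
            nrow(kept), nrow(sim), igraph::vcount(sim_net)))
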