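#!/usr/bin/env Rscript
# Stage 4: MCODE clustering of the C-T network and consensus hub calling.
#
# Runs vertex weighting, seeded expansion and post-processing at the
# published plugin defaults, then intersects the top cluster with the
# topological hub targets to call the consensus hubs.

library(netpharm)

net <- read_sif("results/ct_network.sif")
clusters <- mcode(net)
write_clusters_tsv(clusters, "results/mcode_clusters.tsv")

hub_targets <- read_target_list("results/major_hub_targets.txt")
top_members <- if (length(clusters)) clusters[[1]]$members else character()
consensus_hubs <- intersect_hubs(hub_targets, top_members)
write_target_list(consensus_hubs, "results/consensus_hubs.txt")

cat(sprintf("MCODE found %d clusters; top cluster: %d nodes, score %.2f\n",
            length(clusters),
            if (length(clusters)) clusters[[1]]$size else 0L,
            if (length(clusters)) clusters[[1]]$score else 0))
cat(sprintf("topological hubs %d x top-cluster members %d -> %d consensus hubs\n",
            length(hub_targets), length(top_members), length(consensus_hubs)))
if (length(consensus_hubs)) cat(" ", paste(consensus_hubs, collapse = ", "), "\n")
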