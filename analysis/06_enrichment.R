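#!/usr/bin/env Rscript
# Stage 6: hypergeometric over-representation of the consensus targets.
#
# Tests the consensus target set against the two simulated annotation
# collections under the two conventional significance regimes: p <= 0.01
# for biological processes, p <= 0.05 for pathways (raw p, two-sided).

library(netpharm)

consensus <- read_target_list("results/consensus_targets.txt")
universe <- unique(read_ct_map("results/data/compound_targets.tsv")$target_symbol)

for (run in list(list(gmt = "results/data/bioprocess.gmt", alpha = 0.01,
                      out = "results/enrichment_bioprocess.tsv"),
                 list(gmt = "results/data/pathway.gmt", alpha = 0.05,
                      out = "results/enrichment_pathway.tsv"))) {
  terms <- read_gmt(run$gmt)
  res <- enrich(consensus, terms, universe = universe, alpha = run$alpha)
  write_enrichment_tsv(res, run$out)
  cat(sprintf("%s: %d terms with overlap, %d significant at p <= %.2f\n",
              basename(run$gmt), nrow(res), sum(res$significant), run$alpha))
  print(utils::head(res[c("term_id", "k", "K", "p_value", "significant")], 3),
        digits = 3)
}
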