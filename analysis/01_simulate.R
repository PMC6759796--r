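#!/usr/bin/env Rscript
# Stage 1: generate the complete synthetic study inputs.
#
# The generator emulates the five input kinds of a pharmacokinetics-
# anchored network pharmacology study at its published scale: 29 active
# components whose putative-target union holds 1,288 genes, 812 disease
# candidate targets with 120 of them planted on both sides, a scored PPI
# export over the consensus genes, GMT annotation collections, and
# one-compartment plasma concentration profiles for 6 rats.

library(netpharm)

seed <- 2026L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sp <- synth_spec(rng_seed = seed)
map <- gen_compound_target_map(sp)
disease <- gen_disease_targets(sp)
write_ct_map(map, file.path(out, "compound_targets.tsv"))
write_target_list(disease, file.path(out, "disease_targets.txt"))

consensus <- attr(disease, "planted")
write_edge_tsv(gen_ppi_edges(consensus, density = 0.08, seed = seed + 1L),
               file.path(out, "ppi_edges.tsv"))

# annotation terms span the whole putative-target universe; the first term
# of each collection is planted to be enriched in the consensus genes
all_genes <- sort(unique(map$target_symbol))
plant_term <- function(terms, k_cons, seed_offset) {
  set.seed(seed + seed_offset)
  terms[[1]] <- c(sample(consensus, k_cons),
                  sample(setdiff(all_genes, consensus), 5))
  names(terms)[1] <- "TERM_PLANTED"
  terms
}
write_gmt(plant_term(gen_gmt_terms(all_genes, n_terms = 40,
                                   size_range = c(5, 25), seed = seed + 2L),
                     20, 5L),
          file.path(out, "bioprocess.gmt"))
write_gmt(plant_term(gen_gmt_terms(all_genes, n_terms = 20,
                                   size_range = c(5, 25), seed = seed + 3L),
                     12, 6L),
          file.path(out, "pathway.gmt"))

truth <- pk_truth() # 30% CV lognormal noise, 13-point schedule
prof <- gen_concentration_profiles(truth, n_subjects = 6, seed = seed + 4L)
prof$compound <- "CMP01"
write_conc_csv(prof, file.path(out, "concentrations.csv"))

cat(sprintf(
  "simulated: %d compound-target assertions (%d distinct genes), %d disease targets,\n%d planted consensus genes, %d PPI edges, %d + %d annotation terms, %d PK subjects\n",
  nrow(map), length(unique(map$target_symbol)), length(disease),
  length(consensus), nrow(read_edge_tsv(file.path(out, "ppi_edges.tsv"))),
  40, 20, 6))
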