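small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_compounds = 5, n_targets_universe = 80, targets_per_compound = 4,
         n_disease_targets = 50, planted_overlap = 12, rng_seed = 11L), list(...))
  do.call(synth_spec, args)
}

test_that("spec validation rejects impossible parameter combinations", {
  expect_error(synth_spec(planted_overlap = 2000), "planted_overlap")
  expect_error(synth_spec(ppi_density = 1.2), "ppi_density")
  expect_error(synth_spec(score_range = c(0.9, 0.1)), "score_range")
  expect_error(synth_spec(n_compounds = 50, n_targets_universe = 10), "universe")
})

test_that("generators are deterministic under a fixed spec and seed", {
  sp <- small_spec()
  expect_identical(gen_compound_target_map(sp), gen_compound_target_map(sp))
  expect_identical(gen_disease_targets(sp), gen_disease_targets(sp))
  expect_identical(gen_ppi_edges(letters[1:10], 0.4, seed = 3L),
                   gen_ppi_edges(letters[1:10], 0.4, seed = 3L))
  tr <- pk_truth(noise_cv = 0.2)
  expect_identical(gen_concentration_profiles(tr, 4, seed = 5L),
                   gen_concentration_profiles(tr, 4, seed = 5L))
})

test_that("every compound receives at least one target and the union covers the universe", {
  sp <- small_spec(n_compounds = 2, targets_per_compound = 1, rng_seed = 7L)
  map <- gen_compound_target_map(sp)
  expect_setequal(unique(map$compound_id), c("CMP01", "CMP02"))
  expect_equal(length(unique(normalize_symbol(map$target_symbol))),
               sp$n_targets_universe)
  expect_true(all(table(map$compound_id) >= 1))
})

test_that("duplicate assertions occur across source tags by design", {
  map <- gen_compound_target_map(small_spec(rng_seed = 3L))
  key <- paste(map$compound_id, map$target_symbol)
  multi_source <- tapply(map$source_tag, key, function(s) length(unique(s)) > 1)
  expect_true(any(multi_source))
})

test_that("planted overlap propagates exactly into the consensus intersection", {
  for (overlap in c(0L, 12L, 30L)) {
    sp <- small_spec(planted_overlap = overlap, rng_seed = 21L)
    map <- gen_compound_target_map(sp)
    disease <- gen_disease_targets(sp)
    expect_length(disease, sp$n_disease_targets)
    consensus <- intersect_targets(union_compound_targets(map),
                                   target_set(disease, "disease"))
    expect_length(consensus$symbols, overlap)
    expect_setequal(consensus$symbols, attr(disease, "planted"))
  }
})

test_that("synthetic PPI edge tables are simple, scored in range, density-faithful", {
  genes <- sprintf("g%02d", 1:5)
  expect_equal(nrow(gen_ppi_edges(genes, 0, seed = 1L)), 0L)
  full <- gen_ppi_edges(genes, 1, score_range = c(0.5, 0.8), seed = 1L)
  expect_equal(nrow(full), 10L) # complete graph on 5
  expect_false(any(full$node1 == full$node2))
  expect_false(any(duplicated(paste(pmin(full$node1, full$node2),
                                    pmax(full$node1, full$node2)))))
  expect_true(all(full$score >= 0.5 & full$score <= 0.8))
  expect_error(gen_ppi_edges("one", 0.5), "at least 2")
})

test_that("scores planted to straddle a cutoff filter to the planted count", {
  genes <- sprintf("g%02d", 1:8)
  edges <- gen_ppi_edges(genes, 1, score_range = c(0, 1), seed = 9L)
  n_above <- sum(edges$score >= 0.9)
  expect_equal(nrow(filter_ppi_edges(edges, 0.9)), n_above)
})

test_that("noiseless profiles equal the closed-form curve; peak matches the analytic tmax", {
  tr <- pk_truth(ka = 0.05, ke = 0.005, noise_cv = 0)
  prof <- gen_concentration_profiles(tr, 1, seed = 1L)
  expect_equal(prof$conc, conc_curve(tr, tr$sample_times), tolerance = 1e-12)
  # analytic argmax: ln(ka/ke)/(ka - ke) = ln(10)/0.045
  expect_equal(true_tmax(tr), log(10) / 0.045)
  dense <- seq(1, 300, by = 0.01)
  expect_equal(dense[which.max(conc_curve(tr, dense))], true_tmax(tr),
               tolerance = 1e-4)
  expect_true(all(gen_concentration_profiles(pk_truth(noise_cv = 0.5), 3,
                                             seed = 2L)$conc >= 0))
})

test_that("degenerate or invalid PK truths are rejected", {
  expect_error(pk_truth(ka = 0.01, ke = 0.01), "differ")
  expect_error(pk_truth(ka = -1), "positive")
  expect_error(pk_truth(sample_times = c(10, 5)), "increasing")
  expect_error(gen_concentration_profiles(pk_truth(), 0), "n_subjects")
})

test_that("default spec mirrors the study scale (29 compounds, 1288-gene union, 812 disease, 120 consensus)", {
  sp <- synth_spec(rng_seed = 2L)
  expect_equal(sp$n_compounds, 29L)
  map <- gen_compound_target_map(sp)
  expect_equal(length(unique(map$target_symbol)), 1288L)
  disease <- gen_disease_targets(sp)
  expect_length(disease, 812L)
  consensus <- intersect_targets(union_compound_targets(map),
                                 target_set(disease))
  expect_length(consensus$symbols, 120L)
  tr <- pk_truth()
  expect_equal(tr$sample_times, c(5, 10, 20, 40, 60, 90, 120, 180, 240, 360,
                                  480, 720, 1440))
})
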