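#' Specification for the synthetic study inputs
#'
#' Describes one synthetic "study": how many formula components, how
#' large the putative-target universe they draw from, how many disease
#' candidate targets, and how many targets are *planted* in both sides so
#' the consensus intersection downstream is known by construction. The
#' defaults mirror the scale of a pharmacokinetics-anchored herbal
#' network pharmacology study: 29 components whose putative-target union
#' has 1,288 genes, 812 disease candidates, and 120 shared targets.
#'
#' @param n_compounds number of formula components.
#' @param n_targets_universe size of the putative-target gene universe;
#'   the generated compound-target map covers it exactly, so this is also
#'   the union size. Must be at least `n_compounds`.
#' @param targets_per_compound Poisson mean of *extra* target draws per
#'   compound on top of the covering assignment.
#' @param n_disease_targets disease candidate list size.
#' @param planted_overlap number of universe genes also placed on the
#'   disease list; the downstream consensus intersection equals this
#'   exactly.
#' @param ppi_density edge probability for synthetic PPI graphs.
#' @param score_range range of uniform PPI confidence scores.
#' @param rng_seed integer seed; identical spec + seed gives identical
#'   outputs.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_compounds = 29, n_targets_universe = 1288,
                       targets_per_compound = 15, n_disease_targets = 812,
                       planted_overlap = 120, ppi_density = 0.1,
                       score_range = c(0.4, 1), rng_seed = 1L) {
  if (n_compounds < 1 || n_targets_universe < n_compounds)
    stop("need >= 1 compound and a universe at least as large", call. = FALSE)
  if (targets_per_compound < 0 || n_disease_targets < 0)
    stop("counts must be nonnegative", call. = FALSE)
  if (planted_overlap > min(n_targets_universe, n_disease_targets))
    stop("planted_overlap exceeds the universe or disease list size",
         call. = FALSE)
  if (ppi_density < 0 || ppi_density > 1)
    stop("ppi_density must lie in [0, 1]", call. = FALSE)
  if (length(score_range) != 2 || any(score_range < 0 | score_range > 1) ||
      score_range[1] > score_range[2])
    stop("score_range must be an increasing pair within [0, 1]", call. = FALSE)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_targets_universe = as.integer(n_targets_universe),
                 targets_per_compound = targets_per_compound,
                 n_disease_targets = as.integer(n_disease_targets),
                 planted_overlap = as.integer(planted_overlap),
                 ppi_density = ppi_density, score_range = score_range,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_spec")
}

symbol_universe <- function(spec) {
  width <- max(4L, nchar(as.character(spec$n_targets_universe)))
  sprintf(paste0("G%0", width, "d"), seq_len(spec$n_targets_universe))
}

compound_ids <- function(spec) {
  sprintf("CMP%02d", seq_len(spec$n_compounds))
}

# the planted consensus symbols, derived deterministically from the spec
# so the compound-side and disease-side generators agree without sharing
# state
planted_symbols <- function(spec) {
  if (spec$planted_overlap == 0L) return(character())
  set.seed(spec$rng_seed + 7L)
  sort(sample(symbol_universe(spec), spec$planted_overlap))
}

#' Generate a compound-target assertion table
#'
#' Emulates merged exports from several target databases: every universe
#' gene is assigned to some compound (so the target union equals the
#' universe and every compound has at least one target), each compound
#' draws Poisson-many extra targets, and a fixed 3% of assertions are
#' duplicated under a second source tag to exercise deduplication
#' downstream.
#'
#' @param spec a [synth_spec()].
#' @return data frame with columns `compound_id`, `target_symbol`,
#'   `source_tag`.
#' @export
gen_compound_target_map <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$rng_seed)
  genes <- symbol_universe(spec)
  compounds <- compound_ids(spec)
  sources <- c("drugbank", "swiss", "sea")
  # covering assignment: shuffled genes dealt round-robin to compounds
  dealt <- sample(genes)
  base <- data.frame(
    compound_id = compounds[((seq_along(dealt) - 1L) %% spec$n_compounds) + 1L],
    target_symbol = dealt, stringsAsFactors = FALSE)
  extra_n <- rpois(spec$n_compounds, spec$targets_per_compound)
  extra <- data.frame(
    compound_id = rep(compounds, extra_n),
    target_symbol = sample(genes, sum(extra_n), replace = TRUE),
    stringsAsFactors = FALSE)
  map <- rbind(base, extra)
  map$source_tag <- sample(sources, nrow(map), replace = TRUE)
  n_dup <- floor(0.03 * nrow(map))
  if (n_dup > 0) {
    idx <- sample.int(nrow(map), n_dup)
    dup <- map[idx, , drop = FALSE]
    dup$source_tag <- vapply(dup$source_tag,
                             function(s) sample(setdiff(sources, s), 1L), "")
    map <- rbind(map, dup)
  }
  rownames(map) <- NULL
  map
}

#' Generate a disease candidate target list
#'
#' The list contains the spec's planted symbols (shared with the
#' compound-target universe) plus disease-only symbols (prefix `D`,
#' guaranteed disjoint from the compound universe), deduplicated to
#' exactly `n_disease_targets` entries.
#'
#' @param spec a [synth_spec()].
#' @return sorted character vector of `n_disease_targets` symbols; the
#'   planted subset is attached as attribute `"planted"`.
#' @export
gen_disease_targets <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  planted <- planted_symbols(spec)
  n_only <- spec$n_disease_targets - spec$planted_overlap
  width <- max(4L, nchar(as.character(n_only)))
  only <- if (n_only > 0) sprintf(paste0("D%0", width, "d"), seq_len(n_only))
          else character()
  structure(sort(c(planted, only)), planted = planted)
}

#' Generate a scored PPI edge table
#'
#' Erdos-Renyi edges over the given genes at probability `density`, with
#' confidence scores uniform on `score_range`. Undirected, no self-loops,
#' no duplicate unordered pairs.
#'
#' @param genes character vector of at least 2 gene symbols.
#' @param density edge probability in \[0, 1\].
#' @param score_range increasing pair within \[0, 1\].
#' @param seed integer seed.
#' @return data frame with columns `node1`, `node2`, `score`.
#' @export
gen_ppi_edges <- function(genes, density, score_range = c(0.4, 1), seed = 1L) {
  genes <- unique(as.character(genes))
  if (length(genes) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (density < 0 || density > 1) stop("density must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  pairs <- t(utils::combn(sort(genes), 2L))
  keep <- runif(nrow(pairs)) < density
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(node1 = pairs[, 1], node2 = pairs[, 2],
             score = runif(nrow(pairs), score_range[1], score_range[2]),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic GMT annotation collection
#'
#' Random gene sets drawn from a universe, one term per set, for testing
#' over-representation analysis without external ontologies.
#'
#' @param universe character vector of gene symbols.
#' @param n_terms number of terms.
#' @param size_range inclusive range of term sizes.
#' @param seed integer seed.
#' @return named list of character vectors (GMT-shaped, see [write_gmt()]).
#' @export
gen_gmt_terms <- function(universe, n_terms = 50, size_range = c(10, 60),
                          seed = 1L) {
  stopifnot(n_terms >= 1, size_range[1] >= 1,
            size_range[2] <= length(universe))
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_terms, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(universe, s))
  names(sets) <- sprintf("TERM%04d", seq_len(n_terms))
  sets
}

#' True parameters of a one-compartment oral-absorption model
#'
#' Ground truth for synthetic plasma profiles. The noiseless curve is
#' `C(t) = dose*ka / (V_F*(ka - ke)) * (exp(-ke*t) - exp(-ka*t))` with
#' first-order absorption `ka` and elimination `ke` (both per minute) and
#' apparent volume `V_F`. The default rates give a time-to-peak near
#' 46 min and a terminal half-life near 5 h, the magnitudes typical of
#' orally absorbed herbal constituents; the default sampling grid is the
#' standard 13-point rat schedule (5 to 1440 min post-dose).
#'
#' @param dose administered dose (amount per kg).
#' @param ka absorption rate constant, 1/min.
#' @param ke elimination rate constant, 1/min; must differ from `ka`.
#' @param V_F apparent volume of distribution over bioavailability, in
#'   units making `dose/V_F` a concentration (default tuned so peaks land
#'   near 180 ng/ml).
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   noise (0 = noiseless).
#' @param sample_times strictly increasing sampling times in minutes.
#' @return list of class `pk_truth`.
#' @export
pk_truth <- function(dose = 1.3, ka = 0.08, ke = 0.0023, V_F = 0.0065,
                     noise_cv = 0.30,
                     sample_times = c(5, 10, 20, 40, 60, 90, 120, 180, 240,
                                      360, 480, 720, 1440)) {
  if (ka <= 0 || ke <= 0) stop("ka and ke must be positive", call. = FALSE)
  if (ka == ke) stop("ka must differ from ke (model degenerate)", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be nonnegative", call. = FALSE)
  if (length(sample_times) < 1 || any(diff(sample_times) <= 0) ||
      sample_times[1] < 0)
    stop("sample_times must be strictly increasing and start at >= 0",
         call. = FALSE)
  structure(list(dose = dose, ka = ka, ke = ke, V_F = V_F,
                 noise_cv = noise_cv, sample_times = sample_times),
            class = "pk_truth")
}

#' Noiseless one-compartment concentration curve
#'
#' @param truth a [pk_truth()].
#' @param t times in minutes.
#' @return concentrations.
#' @export
conc_curve <- function(truth, t) {
  with(truth, dose * ka / (V_F * (ka - ke)) * (exp(-ke * t) - exp(-ka * t)))
}

#' Closed-form time of peak of the one-compartment curve
#'
#' `tmax = log(ka/ke) / (ka - ke)`, in minutes.
#'
#' @param truth a [pk_truth()].
#' @export
true_tmax <- function(truth) {
  log(truth$ka / truth$ke) / (truth$ka - truth$ke)
}

#' Generate plasma concentration-time profiles
#'
#' Samples the noiseless one-compartment curve at the truth's schedule
#' and applies multiplicative lognormal noise with coefficient of
#' variation `noise_cv` (mean-preserving: the expected concentration at
#' each time equals the curve). Concentrations can never go negative.
#'
#' @param truth a [pk_truth()].
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed.
#' @return data frame with columns `subject`, `time_min`, `conc`.
#' @export
gen_concentration_profiles <- function(truth, n_subjects = 6, seed = 1L) {
  stopifnot(inherits(truth, "pk_truth"), n_subjects >= 1)
  set.seed(seed)
  curve <- conc_curve(truth, truth$sample_times)
  sdlog <- sqrt(log(1 + truth$noise_cv^2))
  rows <- lapply(seq_len(n_subjects), function(s) {
    noise <- if (sdlog > 0)
      exp(rnorm(length(curve), mean = -sdlog^2 / 2, sd = sdlog)) else 1
    data.frame(subject = sprintf("S%02d", s), time_min = truth$sample_times,
               conc = curve * noise, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
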