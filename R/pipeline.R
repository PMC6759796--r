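#' Read a pipeline configuration file
#'
#' YAML with two blocks: `inputs` (paths to the compound-target TSV,
#' disease target list, scored PPI TSV, optional GMT collections and
#' concentration CSV) and `params` (PPI score cutoff, MCODE settings,
#' the two enrichment alpha regimes, NCA options). Relative input paths
#' are resolved against the config file's directory.
#'
#' @param path YAML file.
#' @return a validated config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  cfg$inputs <- lapply(cfg$inputs, function(p) {
    if (is.character(p) && length(p) == 1 && !startsWith(p, "/"))
      file.path(base, p) else p
  })
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a config list (e.g. built in code).
#' @export
validate_pipeline_config <- function(cfg) {
  need <- c("ct_map", "disease_targets", "ppi_edges")
  for (key in need) {
    p <- cfg$inputs[[key]]
    if (is.null(p)) stop("config inputs missing key: ", key, call. = FALSE)
    if (!file.exists(p)) stop("config inputs.", key, ": no such file: ", p,
                              call. = FALSE)
  }
  for (key in c("gmt", "concentrations")) {
    for (p in cfg$inputs[[key]])
      if (!file.exists(p)) stop("config inputs.", key, ": no such file: ", p,
                                call. = FALSE)
  }
  defaults <- list(min_ppi_score = 0.9, alpha_bp = 0.01, alpha_pathway = 0.05,
                   auc_method = "linear", enrichment_sided = "two")
  for (k in names(defaults))
    if (is.null(cfg$params[[k]])) cfg$params[[k]] <- defaults[[k]]
  cfg$params$mcode <- do.call(mcode_params, as.list(cfg$params$mcode))
  cfg
}

#' Run the full network-pharmacology workflow
#'
#' Executes the stages in study order -- consensus targets, C-T network,
#' topological hub extraction, MCODE clustering, consensus hub calling,
#' confidence-filtered PPI subnetwork with its topology table, and
#' (optionally) over-representation analysis and NCA -- writing one TSV
#' per stage plus a JSON manifest of input hashes, parameters and the
#' stage counts a study report quotes. Identical config and inputs give
#' an identical manifest.
#'
#' @param cfg config list from [read_pipeline_config()] /
#'   [validate_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  cfg <- validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(out_dir, f)

  # stage 1: consensus targets
  ct_map <- read_ct_map(cfg$inputs$ct_map)
  disease <- target_set(read_target_list(cfg$inputs$disease_targets), "disease")
  cmp_union <- union_compound_targets(ct_map)
  consensus <- intersect_targets(cmp_union, disease, name = "consensus")
  write_target_list(consensus$symbols, out("consensus_targets.txt"))

  # stage 2: C-T network
  ct_net <- build_ct_network(ct_map, consensus)
  write_sif(ct_net, out("ct_network.sif"))
  write_graphml(ct_net, out("ct_network.graphml"))

  # stage 3: topology + major hub extraction
  topo <- node_topology(ct_net)
  write_topology_tsv(topo, out("ct_topology.tsv"))
  hubnet <- extract_major_hub_network(ct_net)
  hub_targets <- intersect(hubnet$nodes, network_part(ct_net, "target"))
  hub_compounds <- intersect(hubnet$nodes, network_part(ct_net, "compound"))
  write_target_list(sort(hub_targets), out("major_hub_targets.txt"))

  # stage 4: MCODE clustering
  clusters <- mcode(ct_net, cfg$params$mcode)
  write_clusters_tsv(clusters, out("mcode_clusters.tsv"))
  top_members <- if (length(clusters)) clusters[[1]]$members else character()

  # stage 5: consensus hubs
  consensus_hubs <- intersect_hubs(hub_targets, top_members)
  write_target_list(consensus_hubs, out("consensus_hubs.txt"))

  # stage 6: PPI subnetwork
  ppi_raw <- read_edge_tsv(cfg$inputs$ppi_edges)
  ppi_edges <- filter_ppi_edges(ppi_raw, cfg$params$min_ppi_score)
  ppi_net <- build_ppi_network(ppi_edges, consensus_hubs)
  write_sif(ppi_net, out("ppi_network.sif"))
  ppi_topo <- node_topology(ppi_net)
  write_topology_tsv(ppi_topo, out("ppi_topology.tsv"))

  # stage 7: enrichment (optional)
  n_signif <- NA_integer_
  if (length(cfg$inputs$gmt)) {
    n_signif <- 0L
    for (gpath in cfg$inputs$gmt) {
      terms <- read_gmt(gpath)
      alpha <- if (grepl("pathway", basename(gpath), ignore.case = TRUE))
        cfg$params$alpha_pathway else cfg$params$alpha_bp
      res <- enrich(consensus, terms, alpha = alpha,
                    sided = cfg$params$enrichment_sided)
      write_enrichment_tsv(res, out(paste0(
        "enrichment_", sub("\\.gmt$", "", basename(gpath)), ".tsv")))
      n_signif <- n_signif + sum(res$significant)
    }
  }

  # stage 8: NCA (optional)
  if (!is.null(cfg$inputs$concentrations)) {
    pk <- summarize_pk(read_conc_csv(cfg$inputs$concentrations),
                       auc_method = cfg$params$auc_method)
    write.table(pk, out("pk_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  manifest <- list(
    inputs = lapply(cfg$inputs, function(p)
      if (is.character(p)) unname(tools::md5sum(p)) else p),
    params = cfg$params[setdiff(names(cfg$params), "mcode")],
    mcode = unclass(cfg$params$mcode),
    counts = list(
      compound_target_assertions = nrow(ct_map),
      putative_target_union = length(cmp_union$symbols),
      disease_targets = length(disease$symbols),
      consensus_targets = length(consensus$symbols),
      ct_nodes = igraph::vcount(ct_net),
      ct_edges = igraph::ecount(ct_net),
      hub_threshold = hubnet$threshold,
      major_hub_targets = length(hub_targets),
      major_hub_compounds = length(hub_compounds),
      n_clusters = length(clusters),
      top_cluster_size = if (length(clusters)) clusters[[1]]$size else 0L,
      consensus_hubs = length(consensus_hubs),
      ppi_nodes = igraph::vcount(ppi_net),
      ppi_edges = igraph::ecount(ppi_net),
      significant_terms = n_signif))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
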