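#' @name netpharm-io
#' @title Readers and writers for the pipeline interchange formats
#'
#' @description All interchange is plain text, UTF-8, tab-delimited where
#' columnar: compound-target assertion TSV (`compound_id`, `target_symbol`,
#' `source_tag`), one-symbol-per-line target lists, STRING-style scored
#' edge TSV (`node1`, `node2`, `score`), SIF and GraphML for networks, GMT
#' (Broad convention) for annotation gene sets, and concentration CSV
#' (`subject`, `time_min`, `conc`) for pharmacokinetic profiles.
NULL

#' Read / write a compound-target assertion table
#'
#' @param path file path.
#' @return data frame with columns `compound_id`, `target_symbol`,
#'   `source_tag`.
#' @export
read_ct_map <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "target_symbol", "source_tag")
  if (!all(need %in% names(x)))
    stop("compound-target TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x[need]
}

#' @rdname read_ct_map
#' @param ct_map data frame as returned by [gen_compound_target_map()].
#' @export
write_ct_map <- function(ct_map, path) {
  write.table(ct_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a one-symbol-per-line target list
#'
#' Blank lines are skipped; symbols are returned raw (normalize with
#' [normalize_symbol()] or wrap in [target_set()]).
#'
#' @param path file path.
#' @export
read_target_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' @rdname read_target_list
#' @param symbols character vector.
#' @export
write_target_list <- function(symbols, path) {
  writeLines(symbols, path)
  invisible(path)
}

#' Read / write a scored edge table (STRING-style TSV)
#'
#' Columns `node1`, `node2`, `score` with score in \[0, 1\]. Used both for
#' raw PPI exports and for confidence-filtered edge sets.
#'
#' @param path file path.
#' @return data frame with columns `node1`, `node2`, `score`.
#' @export
read_edge_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("node1", "node2", "score")
  if (!all(need %in% names(x)))
    stop("scored edge TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x <- x[need]
  if (any(!is.finite(x$score)) || any(x$score < 0 | x$score > 1))
    stop("edge scores must lie in [0, 1]", call. = FALSE)
  x
}

#' @rdname read_edge_tsv
#' @param edges data frame with columns `node1`, `node2`, `score`.
#' @export
write_edge_tsv <- function(edges, path) {
  write.table(edges[c("node1", "node2", "score")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write networks in SIF
#'
#' SIF rows are `node1<TAB>relation<TAB>node2`; an isolated node is a row
#' with the bare node name (the Cytoscape convention). Compound-target
#' edges use relation `ct`, protein-protein edges use `pp`. On reading,
#' node parts are reconstructed from the relation word where possible.
#'
#' @param graph an igraph object; a `part` vertex attribute
#'   (`"compound"`/`"target"`) selects the `ct` relation, otherwise `pp`
#'   is written.
#' @param path file path.
#' @export
write_sif <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  rel <- rep("pp", nrow(el))
  if ("part" %in% igraph::vertex_attr_names(graph)) {
    part <- setNames(igraph::V(graph)$part, igraph::V(graph)$name)
    is_ct <- part[el[, 1]] != part[el[, 2]]
    rel[is_ct] <- "ct"
    # write compound first for ct rows, for stable round-trips
    flip <- is_ct & part[el[, 1]] != "compound"
    el[flip, ] <- el[flip, c(2, 1)]
  }
  lines <- if (nrow(el)) paste(el[, 1], rel, el[, 2], sep = "\t") else character()
  isolated <- igraph::V(graph)$name[igraph::degree(graph) == 0]
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(igraph::make_empty_graph(directed = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(!lengths(parts) %in% c(1L, 3L))
  if (length(bad))
    stop("malformed SIF line ", bad[1], ": expected 1 or 3 tab-separated fields",
         call. = FALSE)
  lone <- vapply(parts, length, 0L) == 1L
  el <- do.call(rbind, parts[!lone])
  if (is.null(el)) {
    g <- igraph::make_empty_graph(directed = FALSE)
    if (any(lone)) g <- igraph::add_vertices(g, sum(lone),
                                             name = unlist(parts[lone]))
    return(g)
  }
  g <- igraph::graph_from_edgelist(el[, c(1, 3), drop = FALSE], directed = FALSE)
  if (any(lone)) {
    extra <- setdiff(unlist(parts[lone]), igraph::V(g)$name)
    if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  rel <- el[, 2]
  igraph::E(g)$relation <- rel
  if (any(rel == "ct")) {
    part <- rep(NA_character_, igraph::vcount(g))
    names(part) <- igraph::V(g)$name
    part[el[rel == "ct", 1]] <- "compound"
    part[el[rel == "ct", 3]] <- "target"
    part[is.na(part)] <- "target"
    igraph::V(g)$part <- part
  }
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Read / write networks in GraphML
#'
#' Thin wrappers over igraph's GraphML support; node attributes (including
#' `part`) survive the round trip.
#'
#' @param graph igraph object.
#' @param path file path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Read / write GMT gene-set collections
#'
#' Broad convention: one term per line, tab-separated
#' `term_id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return named list of character vectors (member symbols); names are
#'   term ids, a `description` attribute on each element keeps the second
#'   column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": need term, description, >=1 member",
         call. = FALSE)
  sets <- lapply(parts, function(p) structure(p[-(1:2)], description = p[2]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors; an optional `description`
#'   attribute per element becomes the second column.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- names(sets)[i]
    paste(c(names(sets)[i], desc, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write concentration-time profiles
#'
#' CSV with columns `subject`, `time_min`, `conc` (one concentration unit
#' throughout, e.g. ng/ml); an optional `compound` column groups profiles
#' for [summarize_pk()].
#'
#' @param path file path.
#' @export
read_conc_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "time_min", "conc")
  if (!all(need %in% names(x)))
    stop("concentration CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x
}

#' @rdname read_conc_csv
#' @param profiles data frame as from [gen_concentration_profiles()].
#' @export
write_conc_csv <- function(profiles, path) {
  write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
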