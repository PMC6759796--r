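#' Normalize a gene/protein symbol
#'
#' Symbols arriving from different databases disagree on case and
#' punctuation (the same interleukin appears as "IL-6" and "IL6").
#' Normalization uppercases, strips hyphens and trims surrounding
#' whitespace, and is idempotent, so set operations on symbols from mixed
#' sources are well defined.
#'
#' @param raw character vector of raw symbols; empty strings are an error.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_symbol(c("IL-6", "vegfa")) # "IL6" "VEGFA"
#' @export
normalize_symbol <- function(raw) {
  if (!is.character(raw)) stop("symbols must be character", call. = FALSE)
  out <- toupper(gsub("-", "", trimws(raw), fixed = TRUE))
  if (any(!nzchar(out))) stop("empty symbol after normalization", call. = FALSE)
  out
}

#' Construct a named target set
#'
#' A target set is a deduplicated, normalized set of gene symbols with a
#' provenance label, the unit on which intersections and enrichment
#' queries operate.
#'
#' @param symbols character vector of gene symbols (normalized internally).
#' @param name label for the set.
#' @param provenance free-text source tag.
#' @return object of class `target_set`.
#' @export
target_set <- function(symbols, name = "targets", provenance = NA_character_) {
  symbols <- if (length(symbols)) sort(unique(normalize_symbol(symbols))) else character()
  structure(list(name = name, symbols = symbols, provenance = provenance),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set '%s': %d symbols", x$name, length(x$symbols)))
  if (!is.na(x$provenance)) cat(sprintf(" [%s]", x$provenance))
  cat(">\n")
  invisible(x)
}

#' @export
length.target_set <- function(x) length(x$symbols)

#' Union of putative targets across all compounds and source databases
#'
#' Collapses a compound-target assertion table (one row per
#' compound/target/source triple) to the deduplicated union of target
#' symbols, the "putative target" side of the consensus intersection.
#'
#' @param ct_map data frame with columns `compound_id`, `target_symbol`
#'   (and optionally `source_tag`, ignored here).
#' @param name label for the resulting set.
#' @return a [target_set].
#' @export
union_compound_targets <- function(ct_map, name = "compound_targets") {
  stopifnot(is.data.frame(ct_map))
  if (nrow(ct_map) == 0L) stop("compound-target table is empty", call. = FALSE)
  if (!all(c("compound_id", "target_symbol") %in% names(ct_map)))
    stop("need columns compound_id, target_symbol", call. = FALSE)
  target_set(ct_map$target_symbol, name = name, provenance = "union over compounds")
}

#' Intersect two target sets
#'
#' The consensus step: targets asserted for the formula's components that
#' are also disease candidates. Commutative and idempotent.
#'
#' @param a,b [target_set] objects (or character vectors, coerced).
#' @param name label for the result.
#' @return a [target_set].
#' @export
intersect_targets <- function(a, b, name = "consensus") {
  a <- as_target_set(a)
  b <- as_target_set(b)
  target_set(intersect(a$symbols, b$symbols), name = name,
             provenance = paste(a$name, "&", b$name))
}

as_target_set <- function(x) {
  if (inherits(x, "target_set")) x else target_set(x, name = deparse(substitute(x)))
}
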