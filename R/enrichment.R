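#' Hypergeometric tail p-value for set overlap
#'
#' For a universe of `N` genes of which `K` carry an annotation, and a
#' query of `n` genes of which `k` carry it, the one-sided p-value is the
#' upper tail `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`; the
#' two-sided p-value doubles the smaller of the upper tail `P(X >= k)`
#' and the lower tail `P(X <= k)`, capped at 1.
#'
#' @param k overlap count.
#' @param K annotated genes in the universe (term size).
#' @param n query size within the universe.
#' @param N universe size.
#' @param sided `"one"` or `"two"`.
#' @return p-value in (0, 1].
#' @export
hypergeometric_p <- function(k, K, n, N, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (any(K > N) || any(n > N) || any(k > pmin(K, n)) || any(k < 0))
    stop("inconsistent hypergeometric counts", call. = FALSE)
  upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  if (sided == "one") return(upper)
  lower <- phyper(k, K, N - K, n, lower.tail = TRUE)
  pmin(1, 2 * pmin(upper, lower))
}

#' Over-representation analysis of a target set against GMT terms
#'
#' Tests each annotation term for over-representation of the query in
#' the universe with a hypergeometric test (two-sided by default, as
#' ClueGO-style analyses use). Query symbols outside the universe are
#' dropped with a warning; terms with no overlap (`k = 0`) are excluded.
#' Significance is `p <= alpha` (inclusive); results are sorted by p
#' ascending with term id breaking ties. Two conventional alpha regimes
#' exist downstream: 0.01 for biological processes, 0.05 for pathways.
#'
#' @param query [target_set] or character vector of query symbols.
#' @param terms named list of character vectors (e.g. from [read_gmt()]).
#' @param universe optional [target_set]/character vector; defaults to
#'   the union of all term members.
#' @param alpha significance level in (0, 1).
#' @param sided `"two"` (default) or `"one"`.
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"` (raw-p filtering), `"BH"`
#'   available as an opt-in.
#' @return data frame with columns `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `p_value`, `significant`.
#' @export
enrich <- function(query, terms, universe = NULL, alpha = 0.05,
                   sided = c("two", "one"), p_adjust = "none") {
  sided <- match.arg(sided)
  stopifnot(alpha > 0, alpha < 1, length(terms) > 0)
  term_members <- lapply(terms, normalize_symbol)
  uni <- if (is.null(universe)) unique(unlist(term_members))
         else as_target_set(universe)$symbols
  if (length(uni) == 0L) stop("empty universe", call. = FALSE)
  q <- as_target_set(query)$symbols
  outside <- setdiff(q, uni)
  if (length(outside)) {
    warning(length(outside), " query symbol(s) outside the universe dropped")
    q <- intersect(q, uni)
  }
  n <- length(q)
  N <- length(uni)
  rows <- lapply(seq_along(terms), function(i) {
    members <- intersect(unique(term_members[[i]]), uni)
    k <- length(intersect(q, members))
    if (k == 0L) return(NULL)
    desc <- attr(terms[[i]], "description")
    data.frame(term_id = names(terms)[i],
               term_name = if (is.null(desc)) names(terms)[i] else desc,
               k = k, K = length(members), n = n, N = N,
               p_value = hypergeometric_p(k, length(members), n, N, sided),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_value <- p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value <= alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment result table as TSV
#'
#' @param result data frame from [enrich()].
#' @param path file path.
#' @export
write_enrichment_tsv <- function(result, path) {
  write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
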