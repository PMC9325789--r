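#' Upper-tail hypergeometric over-representation probability
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' sampled without replacement from a universe of `N` genes of which `K`
#' carry the annotation: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`, inclusive of `k`.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Annotated genes in the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return The one-sided p-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k < 0 || k > min(K, n))
    stop("impossible overlap: k = ", k, " with K = ", K, ", n = ", n)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation of a query set across an annotation collection
#'
#' Tests each term for enrichment of the query genes under the
#' hypergeometric distribution. Terms are intersected with the universe
#' first; terms left empty are excluded from testing and from the
#' multiple-testing denominator. Benjamini-Hochberg q-values are computed
#' over all tested terms.
#'
#' @param query Character vector of genes (non-empty, subset of `universe`).
#' @param sets A [gene_set_collection()].
#' @param universe Character vector: the gene universe (e.g. all scored
#'   genes carrying at least one annotation).
#' @return Data frame sorted by ascending p: `term_id`, `term_name`, `k`
#'   (overlap), `K` (term size in universe), `n` (query size), `N`
#'   (universe size), `p`, `q`.
#' @export
enrich_all <- function(query, sets, universe) {
  stopifnot(inherits(sets, "gene_set_collection"))
  query <- unique(as.character(query))
  if (!length(query)) stop("empty query gene set")
  universe <- unique(as.character(universe))
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene(s) outside universe: ", paste(outside, collapse = ", "))
  members <- lapply(sets$sets, intersect, universe)
  keep <- lengths(members) >= 1L
  if (!any(keep)) stop("no term overlaps the universe")
  members <- members[keep]
  N <- length(universe); n <- length(query)
  K <- lengths(members)
  k <- vapply(members, function(m) length(intersect(m, query)), 0L)
  p <- mapply(hypergeom_test, k = k, K = K, MoreArgs = list(n = n, N = N))
  out <- data.frame(term_id = names(members),
                    term_name = unname(sets$term_names[names(members)]),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p = unname(p), stringsAsFactors = FALSE, row.names = NULL)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
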