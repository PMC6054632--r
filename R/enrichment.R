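# Gene-set over-representation analysis (hypergeometric upper tail + BH).

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` are annotated. Computed via
#' the log-space survival function of [stats::phyper].
#'
#' @param k observed overlap (0 <= k <= min(n, K)).
#' @param K annotated genes in the universe.
#' @param n query-list size.
#' @param N universe size.
#' @return p in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  for (v in list(k, K, n, N)) {
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      stop_brustab("k, K, n, N must be non-negative integers")
    }
  }
  if (any(K > N) || any(n > N) || any(k > pmin(n, K))) {
    stop_brustab("inconsistent counts: need K <= N, n <= N, k <= min(n, K)")
  }
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Over-representation analysis of a gene list against a collection
#'
#' One hypergeometric upper-tail test per gene set (set membership
#' intersected with the universe), BH adjustment across tested sets,
#' sorted by q then p. Query genes outside the universe are dropped with
#' a warning giving the count.
#'
#' @param query_genes character vector (e.g. destabilized transcripts).
#' @param gene_sets named list of gene-id vectors.
#' @param universe_genes background gene ids (must be non-empty).
#' @param enrichment_fdr significance threshold on q (default 0.05).
#' @return Data frame `set_name`, `k`, `n`, `K`, `N`, `fold_enrichment`,
#'   `p`, `q`, `significant`.
#' @export
ora_analysis <- function(query_genes, gene_sets, universe_genes,
                         enrichment_fdr = 0.05) {
  universe <- unique(universe_genes)
  if (!length(universe)) stop_brustab("universe is empty")
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe were dropped",
                    length(outside)), call. = FALSE)
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- if (K == 0L) 1 else hypergeom_upper_tail(k, K, n, N)
    data.frame(set_name = nm, k = k, n = n, K = K, N = N,
               fold_enrichment = if (n > 0 && K > 0) (k / n) / (K / N) else 0,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < enrichment_fdr
  out[order(out$q, out$p, out$set_name), , drop = FALSE]
}
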