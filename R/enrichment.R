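# Hypergeometric over-representation of candidate genes in literature
# catalogs (one-sided upper tail).  The gene universe is a required
# explicit input: reported p-values depend on it and no silent default
# is assumed.

#' Hypergeometric upper-tail probability
#'
#' Exact probability of drawing at least `k` catalog genes when `n`
#' genes are drawn without replacement from a universe of `N` genes of
#' which `K` are in the catalog:
#' \deqn{P(X \ge k) = \sum_{j \ge k} \binom{K}{j}\binom{N-K}{n-j} / \binom{N}{n}.}
#'
#' @param N Universe size.
#' @param K Catalog size within the universe.
#' @param n Query (draw) size.
#' @param k Observed overlap.
#' @return Upper-tail probability in (0, 1].
#' @export
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 2)  # 155/210
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n)) {
    .stopf("hypergeom_upper_tail: inconsistent counts (N=%s K=%s n=%s k=%s)", N, K, n, k)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-catalog over-representation test
#'
#' Tests whether a query gene list is over-represented in a catalog of
#' literature genes, relative to an explicit gene universe.  Symbols are
#' matched case-insensitively after whitespace stripping; query or
#' catalog genes outside the universe are dropped with a warning.
#'
#' @param query_genes Character vector of candidate genes (e.g. genes
#'   carrying flagged SNPs).
#' @param catalog_genes Character vector of catalog genes.
#' @param universe_genes Character vector: the gene universe (e.g. all
#'   annotated genes); must be non-empty.
#' @return Object of class `enrichment_result` with fields `N`, `K`,
#'   `n`, `k`, `p_value` and the overlapping gene symbols.
#' @export
enrich <- function(query_genes, catalog_genes, universe_genes) {
  norm <- function(x) unique(toupper(trimws(x)))
  universe <- norm(universe_genes)
  if (length(universe) == 0L) .stopf("enrich: empty gene universe")
  query <- norm(query_genes)
  catalog <- norm(catalog_genes)
  out_q <- setdiff(query, universe)
  out_c <- setdiff(catalog, universe)
  if (length(out_q) > 0L) {
    warning(sprintf("enrich: %d query gene(s) outside the universe dropped", length(out_q)))
  }
  if (length(out_c) > 0L) {
    warning(sprintf("enrich: %d catalog gene(s) outside the universe dropped", length(out_c)))
  }
  query <- intersect(query, universe)
  catalog <- intersect(catalog, universe)
  overlap <- intersect(query, catalog)
  res <- list(N = length(universe), K = length(catalog), n = length(query),
              k = length(overlap),
              p_value = hypergeom_upper_tail(length(universe), length(catalog),
                                             length(query), length(overlap)),
              overlap_genes = sort(overlap))
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("hypergeometric over-representation: k = %d of n = %d query genes in a catalog of K = %d (universe N = %d)\n",
              x$k, x$n, x$K, x$N))
  cat(sprintf("  upper-tail p = %.4g\n", x$p_value))
  invisible(x)
}
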