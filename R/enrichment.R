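# Hypergeometric over-representation of a query gene set against annotated
# gene sets, with the reporting filters used throughout the pipeline.

#' Hypergeometric gene-set enrichment
#'
#' For each gene set (after removing excluded set ids and intersecting with
#' the universe), computes the upper-tail hypergeometric probability
#' `P(X >= k)` of drawing `k` or more set genes in a query of size `n` from a
#' universe of size `N` containing `K` set genes. Raw p-values are filtered at
#' `p < p_max` and `k >= min_count` and results are sorted ascending by p.
#' No multiple-testing correction is applied to the filter; a
#' Benjamini-Hochberg FDR column over all tested sets is reported for
#' context.
#'
#' @param query Character vector of query gene ids (subset of `universe`).
#' @param universe Character vector of background gene ids.
#' @param gene_sets Named list of character vectors of gene ids.
#' @param p_max Raw p-value cutoff (default 0.05).
#' @param min_count Minimum overlap count (default 3).
#' @param exclusions Set ids never tested (default none).
#' @param filter If `FALSE`, return all tested sets unfiltered.
#' @return Data frame with `set_id`, `k`, `K`, `n`, `N`, `p`, `bh_fdr`,
#'   sorted by `p`. Empty when `gene_sets` is empty or nothing passes.
#' @export
hypergeom_enrich <- function(query, universe, gene_sets, p_max = 0.05,
                             min_count = 3L, exclusions = character(),
                             filter = TRUE) {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  if (length(setdiff(query, universe)))
    stop("query contains genes absent from the universe")
  empty <- data.frame(set_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      bh_fdr = numeric())
  gene_sets <- gene_sets[setdiff(names(gene_sets), exclusions)]
  if (!length(gene_sets)) return(empty)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(gene_sets[[id]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k = k, K = K, n = n, N = N, p = p)
  })
  df <- do.call(rbind, rows)
  df$bh_fdr <- stats::p.adjust(df$p, method = "BH")
  if (filter) df <- df[df$p < p_max & df$k >= min_count, , drop = FALSE]
  df <- df[order(df$p, df$set_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
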