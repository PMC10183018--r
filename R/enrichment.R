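#' Partition two gene sets into shared and exclusive fractions
#'
#' @param a,b Character vectors of gene identifiers (duplicates
#'   ignored). At least one must be non-empty.
#' @return A one-row `data.frame`: counts `n_shared`, `n_a_only`,
#'   `n_b_only` and percentages of the union `pct_shared`,
#'   `pct_a_only`, `pct_b_only`, rounded to one decimal.
#' @examples
#' compareGeneSets(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
#' @export
compareGeneSets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b))
    stop("both gene sets are empty")
  setPartition(length(intersect(a, b)),
               length(setdiff(a, b)),
               length(setdiff(b, a)))
}

#' Set partition from printed counts
#'
#' @param n_shared,n_a_only,n_b_only Non-negative counts of shared and
#'   exclusive members.
#' @return Same shape as [compareGeneSets()].
#' @examples
#' setPartition(282, 1153, 2731)   # 6.8 / 27.7 / 65.6
#' @export
setPartition <- function(n_shared, n_a_only, n_b_only) {
  if (any(c(n_shared, n_a_only, n_b_only) < 0))
    stop("counts must be non-negative")
  union_n <- n_shared + n_a_only + n_b_only
  if (union_n == 0) stop("both gene sets are empty")
  data.frame(n_shared = n_shared, n_a_only = n_a_only,
             n_b_only = n_b_only,
             pct_shared = round(100 * n_shared / union_n, 1),
             pct_a_only = round(100 * n_a_only / union_n, 1),
             pct_b_only = round(100 * n_b_only / union_n, 1))
}

#' Hypergeometric gene-set over-representation test
#'
#' One-sided upper-tail test per term: for a query of size `n` drawn
#' from a universe of size `N` containing `K` term members, the
#' probability of observing `k` or more members in the query,
#' `P(X >= k)`. Terms with no query overlap are omitted. q-values are
#' Benjamini-Hochberg-adjusted across all tested terms.
#'
#' @param query Character vector of gene ids; must be a subset of
#'   `universe`.
#' @param termMap Named list term -> character vector of member genes;
#'   members are intersected with the universe.
#' @param universe Character vector: the gene universe (by default the
#'   full annotation should be supplied).
#' @return `data.frame` sorted by (q, p) with columns `term_id`, `k`,
#'   `n`, `K`, `N`, `p`, `q`.
#' @export
hypergeomEnrichment <- function(query, termMap, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) stop("universe is empty")
  off <- setdiff(query, universe)
  if (length(off))
    stop("query gene(s) not in universe: ",
         paste(head(off, 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(termMap), function(tm) {
    members <- intersect(unique(termMap[[tm]]), universe)
    K <- length(members)
    k <- length(intersect(members, query))
    if (k < 1L) return(NULL)
    data.frame(term_id = tm, k = k, n = n, K = K, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p = numeric(0), q = numeric(0)))
  out$q <- bhAdjust(out$p)
  out <- out[order(out$q, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjusted_i = min over j >= i of (p_(j) * m / j)`, capped at 1,
#' returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, element-wise >= `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Read a two-column gene-to-term annotation TSV
#'
#' @param path TSV with columns `gene_id`, `term_id` (no header).
#' @return Named list term -> character vector of genes.
#' @export
readTermMap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("gene_id", "term_id"),
                   stringsAsFactors = FALSE)
  split(df$gene_id, df$term_id)
}
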