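#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing an overlap of at least `r` genes between a query
#' list of size `R` and a gene set of size `n`, drawn without replacement
#' from a universe of `N` genes:
#' `p = sum_{i = r}^{min(n, R)} C(R, i) C(N - R, n - i) / C(N, n)`.
#' Over-representation only (one-sided upper tail). Evaluated through the
#' log-space-stable hypergeometric CDF, exact to double precision.
#'
#' @param r observed overlap count.
#' @param n gene-set size within the universe.
#' @param R query-list size within the universe.
#' @param N universe size.
#' @return the tail probability `P(X >= r)`.
#' @export
hypergeom_tail <- function(r, n, R, N) {
  stopifnot(length(r) == length(n) || length(n) == 1L || length(r) == 1L)
  if (any(r < 0) || any(r > pmin(n, R)))
    stop("invalid overlap: need 0 <= r <= min(n, R), got r=", r[which(r < 0 | r > pmin(n, R))[1]])
  if (any(n > N) || any(R > N))
    stop("invalid sizes: need max(n, R) <= N")
  ifelse(r == 0, 1, phyper(r - 1, R, N - R, n, lower.tail = FALSE))
}

#' Hypergeometric enrichment of a gene list against a collection
#'
#' For each set in the collection, computes the overlap `r` between the
#' query and the set after restricting both to the universe, the in-universe
#' set size `n`, the in-universe query size `R` and the universe size `N`,
#' then the one-sided hypergeometric p-value [hypergeom_tail()] and a
#' Benjamini-Hochberg FDR across all sets of the collection. Query genes
#' outside the universe are dropped (a message reports how many).
#'
#' @param query character vector of gene ids.
#' @param collection a [gene_sets] object.
#' @param universe optional character vector overriding
#'   `collection$universe` (e.g. the measured genes).
#' @param restrict_to_universe if `TRUE`, set members outside the universe
#'   are removed before counting (default `FALSE`: set sizes are counted
#'   against the collection universe as given).
#' @return data frame sorted by `(p, set)` ascending, with columns `set`,
#'   `r`, `n`, `R`, `N`, `p`, `fdr`.
#' @export
enrich <- function(query, collection, universe = NULL,
                   restrict_to_universe = FALSE) {
  stopifnot(inherits(collection, "gene_sets"))
  if (is.null(universe)) universe <- collection$universe
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  dropped <- sum(!query %in% universe)
  if (dropped > 0)
    message(dropped, " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  N <- length(universe)
  R <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    if (restrict_to_universe) members <- intersect(members, universe)
    n <- length(members)
    r <- length(intersect(members, query))
    data.frame(set = nm, r = r, n = n, R = R, N = N,
               p = hypergeom_tail(r, n, R, N), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Names of significantly enriched sets
#' @param result data frame from [enrich()].
#' @param alpha significance level (default 0.05, on the raw p column).
#' @param column `"p"` (default) or `"fdr"`.
#' @export
enriched_sets <- function(result, alpha = 0.05, column = c("p", "fdr")) {
  column <- match.arg(column)
  result$set[result[[column]] <= alpha]
}
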