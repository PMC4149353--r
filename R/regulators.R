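#' Direct expression regulators by over-connectivity
#'
#' A node is a candidate direct regulator of an expression signature when
#' its immediate interaction partners contain more differentially expressed
#' genes than expected by chance. For candidate `v` with neighbour set of
#' size `n` (outgoing by default: a regulator acts on its targets),
#' `r = |neighbours(v) ∩ DEGs|` is tested against a hypergeometric null on a
#' universe of `N = |nodes| - 1` genes (the candidate is excluded from its
#' own universe) with `R = |DEGs \ {v}|` successes. BH FDR across all
#' candidates; ranking by `(p, r descending, gene id)`.
#'
#' @param network an [interaction_network].
#' @param degs character vector of differentially expressed genes. Genes
#'   not in the network are dropped (message).
#' @param mode neighbour direction: `"out"` (default), `"in"` or `"all"`
#'   (undirected, for binding-only networks).
#' @return data frame with columns `gene`, `kind` (`"direct"`), `r`, `n`,
#'   `R`, `N`, `p`, `fdr`, `rank`.
#' @export
direct_regulators <- function(network, degs, mode = c("out", "in", "all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "interaction_network"))
  degs <- unique(degs)
  outside <- setdiff(degs, network$nodes)
  if (length(outside))
    message(length(outside), " DEG(s) not in the network dropped")
  degs <- intersect(degs, network$nodes)
  if (length(degs) == 0L) stop("no DEGs map to the network")
  g <- network$graph
  nodes <- network$nodes
  nb <- igraph::adjacent_vertices(g, v = nodes, mode = mode)
  is_deg <- nodes %in% degs
  n <- integer(length(nodes)); r <- integer(length(nodes))
  for (i in seq_along(nodes)) {
    nbi <- unique(as.integer(nb[[i]]))
    nbi <- nbi[nbi != i]  # a self-loop is not evidence of regulation
    n[i] <- length(nbi)
    r[i] <- sum(is_deg[nbi])
  }
  stats_df <- data.frame(gene = nodes, kind = "direct", r = r, n = n,
                         R = sum(is_deg) - as.integer(is_deg),
                         N = length(nodes) - 1L, stringsAsFactors = FALSE)
  stats_df$p <- hypergeom_tail(stats_df$r, stats_df$n, stats_df$R, stats_df$N)
  stats_df$fdr <- p.adjust(stats_df$p, method = "BH")
  o <- order(stats_df$p, -stats_df$r, stats_df$gene)
  stats_df <- stats_df[o, , drop = FALSE]
  stats_df$rank <- seq_len(nrow(stats_df))
  rownames(stats_df) <- NULL
  stats_df
}

#' Per-node shortest-path traversal counts
#'
#' For each ordered gene pair `(s, t)` with at least one directed path in
#' the network, every shortest `s -> t` path increments the counter of each
#' of its interior nodes by one; endpoints are never counted and
#' unreachable (or identical) pairs contribute nothing. All shortest paths
#' per pair are counted, not one arbitrary representative, so the result is
#' deterministic and order-independent.
#'
#' @param network an [interaction_network].
#' @param pairs two-column matrix or data frame of gene ids (source,
#'   target).
#' @return named numeric vector of traversal counts (one entry per network
#'   node), with attributes `n_paths` (total shortest paths over the pairs)
#'   and `n_paths_interior` (those of length >= 2).
#' @export
ddshortest_path_counts <- function(network, pairs) {
  stopifnot(inherits(network, "interaction_network"))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  adj <- network_adjacency(network)
  if (nrow(pairs) == 0L) {
    out <- setNames(numeric(adj$n), adj$nodes)
    attr(out, "n_paths") <- 0; attr(out, "n_paths_interior") <- 0
    return(out)
  }
  si <- match(pairs[, 1], adj$nodes)
  ti <- match(pairs[, 2], adj$nodes)
  if (anyNA(si) || anyNA(ti)) stop("pair gene not in network")
  keep <- si != ti
  si <- si[keep]; ti <- ti[keep]
  groups <- split(ti - 1L, si)
  sources <- as.integer(names(groups)) - 1L
  targets <- lapply(groups, function(x) as.integer(unique(x)))
  res <- .sp_traversal(adj$n, adj$ptr, adj$idx, sources, unname(targets))
  out <- setNames(res$counts, adj$nodes)
  attr(out, "n_paths") <- res$n_paths
  attr(out, "n_paths_interior") <- res$n_paths_interior
  out
}

#' Remote expression regulators (hidden nodes)
#'
#' Remote regulators sit upstream of the differentially expressed genes:
#' they need not touch any DEG directly but are traversed by an unexpectedly
#' high share of the shortest paths connecting DEG pairs. For each node `v`:
#' `k_v` = number of DEG-pair shortest paths with `v` interior, `K` = total
#' number of DEG-pair shortest paths, `m_v` = number of all-ordered-pair
#' shortest paths with `v` interior, and `M` = total number of all-pairs
#' shortest paths. `v` is flagged when `k_v` is unexpectedly high given
#' `(m_v, K, M)`: `p = hypergeom_tail(k_v, m_v, K, M)`, treating each
#' all-pairs shortest path as a draw unit (so when the DEG set is the whole
#' node set, `K = M`, `k_v = m_v` and every p-value is exactly 1). Nodes
#' with `m_v = 0` are excluded; BH FDR across the candidates; ranking by
#' `(p, k_v descending, gene id)`.
#'
#' Two null models are available. The default analytic null treats each
#' all-pairs traversal as an independent hypergeometric draw; it is fast
#' but anti-conservative on large networks because traversals of one node
#' are strongly correlated (one hub decision redirects thousands of paths).
#' The permutation null (`null = "permutation"`) re-draws `n_perm` node
#' sets of the same size as the DEG set uniformly from the network and
#' recomputes `k_v`; it respects the dependence structure and is the null
#' the pipeline uses to gate the regulator list. Its `tail` can be
#' `"empirical"` (`p = (1 + #\{k_v^perm >= k_v\}) / (n_perm + 1)`; floored
#' at `1 / (n_perm + 1)`, so downstream BH control needs very large
#' `n_perm`) or `"normal"` (upper tail of a z-score against the permutation
#' mean and SD of `k_v`; continuous, so BH across candidates is effective
#' at moderate `n_perm`).
#'
#' @param network an [interaction_network].
#' @param degs character vector of DEGs (>= 2 must map to the network).
#' @param null `"hypergeom"` (default) or `"permutation"`.
#' @param n_perm permutation draws (default 1000).
#' @param perm_seed integer seed for the permutation draws.
#' @param tail for the permutation null: `"empirical"` (default) or
#'   `"normal"`.
#' @return data frame with columns `gene`, `kind` (`"remote"`), `k`, `m`,
#'   `K`, `M`, `p`, `fdr`, `rank`, sorted by rank. Zero connected DEG pairs
#'   yields an empty data frame with a warning.
#' @export
hidden_nodes <- function(network, degs, null = c("hypergeom", "permutation"),
                         n_perm = 1000, perm_seed = NULL,
                         tail = c("empirical", "normal")) {
  null <- match.arg(null)
  tail <- match.arg(tail)
  stopifnot(inherits(network, "interaction_network"))
  degs <- intersect(unique(degs), network$nodes)
  if (length(degs) < 2L) stop("need >= 2 DEGs in the network")
  adj <- network_adjacency(network)
  di <- match(degs, adj$nodes) - 1L
  res_d <- .sp_traversal(adj$n, adj$ptr, adj$idx, as.integer(di),
                         rep(list(as.integer(di)), length(di)))
  if (res_d$n_paths == 0) {
    warning("no DEG pair is connected by a directed path")
    return(data.frame(gene = character(), kind = character(), k = numeric(),
                      m = numeric(), K = numeric(), M = numeric(),
                      p = numeric(), fdr = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  all_idx <- seq_len(adj$n) - 1L
  res_a <- .sp_traversal(adj$n, adj$ptr, adj$idx, as.integer(all_idx),
                         rep(list(as.integer(all_idx)), adj$n))
  k <- res_d$counts
  m <- res_a$counts
  K <- res_d$n_paths
  M <- res_a$n_paths
  cand <- which(m > 0)
  df <- data.frame(gene = adj$nodes[cand], kind = "remote",
                   k = k[cand], m = m[cand], K = K, M = M,
                   stringsAsFactors = FALSE)
  if (null == "hypergeom") {
    df$p <- vapply(seq_len(nrow(df)),
                   function(i) hypergeom_tail(df$k[i], df$m[i], df$K[i], df$M[i]),
                   0)
  } else {
    if (!is.null(perm_seed)) set.seed(perm_seed)
    exceed <- numeric(nrow(df))
    sum1 <- numeric(nrow(df)); sum2 <- numeric(nrow(df))
    n_nodes <- adj$n
    d <- length(di)
    for (b in seq_len(n_perm)) {
      pi <- sample.int(n_nodes, d) - 1L
      res_b <- .sp_traversal(adj$n, adj$ptr, adj$idx, as.integer(pi),
                             rep(list(as.integer(pi)), d))
      kb <- res_b$counts[cand]
      exceed <- exceed + (kb >= df$k)
      sum1 <- sum1 + kb
      sum2 <- sum2 + kb * kb
    }
    mu <- sum1 / n_perm
    sd_b <- sqrt(pmax(0, sum2 / n_perm - mu^2) * n_perm / (n_perm - 1))
    df$perm_mean <- mu
    df$perm_sd <- sd_b
    if (tail == "empirical") {
      df$p <- (1 + exceed) / (n_perm + 1)
    } else {
      z <- ifelse(sd_b > 0, (df$k - mu) / sd_b,
                  ifelse(df$k > mu, Inf, 0))
      df$z <- z
      df$p <- pnorm(z, lower.tail = FALSE)
    }
  }
  df$fdr <- p.adjust(df$p, method = "BH")
  o <- order(df$p, -df$k, df$gene)
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Combined regulator list
#'
#' The pipeline's "expression regulators" are the union of significant
#' direct regulators and significant hidden nodes.
#'
#' @param direct data frame from [direct_regulators()].
#' @param remote data frame from [hidden_nodes()].
#' @param alpha significance level (default 0.05).
#' @param column `"fdr"` (default) or `"p"`.
#' @return character vector of regulator gene ids (sorted).
#' @export
regulator_genes <- function(direct, remote = NULL, alpha = 0.05,
                            column = c("fdr", "p")) {
  column <- match.arg(column)
  out <- direct$gene[direct[[column]] <= alpha]
  if (!is.null(remote) && nrow(remote) > 0)
    out <- union(out, remote$gene[remote[[column]] <= alpha])
  sort(out)
}
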