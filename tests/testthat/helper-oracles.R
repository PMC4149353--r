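# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the hypergeometric oracle enumerates draws
# explicitly, and the shortest-path oracle expands igraph's per-pair path
# lists instead of the package's sigma/suffix accumulation.

# exact upper-tail overlap probability by enumerating every C(N, n) draw of
# the gene set against a reference query of size R
enum_hyper_tail <- function(r, n, R, N) {
  if (r == 0) return(1)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= R)  # reference = elements 1..R
  sum(overlaps >= r) / ncol(draws)
}

# per-node interior traversal counts by brute-force expansion of all
# shortest paths for each ordered pair
brute_sp_counts <- function(network, pairs) {
  g <- network$graph
  counts <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  n_paths <- 0
  for (i in seq_len(nrow(pairs))) {
    s <- pairs[i, 1]; t <- pairs[i, 2]
    if (s == t) next
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = s, to = t, mode = "out"))$vpaths
    for (p in sp) {
      nm <- igraph::V(g)$name[as.integer(p)]
      n_paths <- n_paths + 1
      if (length(nm) > 2)
        counts[nm[-c(1, length(nm))]] <- counts[nm[-c(1, length(nm))]] + 1
    }
  }
  attr(counts, "n_paths") <- n_paths
  counts
}

# classical pooled-variance two-sample t, coded directly from the textbook
# formula
pooled_t_oracle <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m2 - m1) / sqrt(s2 * (1 / n1 + 1 / n2))
}

# random directed graph as an interaction_network
random_digraph <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pool <- expand.grid(s = seq_len(n_nodes), t = seq_len(n_nodes))
  pool <- pool[pool$s != pool$t, ]
  pick <- pool[sample.int(nrow(pool), min(n_edges, nrow(pool))), ]
  edges <- data.frame(source = nodes[pick$s], target = nodes[pick$t],
                      effect = "activation", mechanism = "binding",
                      stringsAsFactors = FALSE)
  interaction_network(edges, nodes = nodes)
}

# small fully-annotated pathway topology used by the cascade tests:
# L -> R -> K1 -> K2 -> TF1 and a branch K1 -> K3 -> TF2
toy_topology <- function() {
  list(
    topology = data.frame(
      source = c("L", "R", "K1", "K2", "K1", "K3"),
      target = c("R", "K1", "K2", "TF1", "K3", "TF2"),
      effect = "activation", mechanism = "other",
      stringsAsFactors = FALSE),
    roles = data.frame(
      gene = c("L", "R", "K1", "K2", "K3", "TF1", "TF2"),
      role = c("ligand", "receptor", "transducer", "transducer",
               "transducer", "transcription-factor", "transcription-factor"),
      blood_expressed = FALSE, stringsAsFactors = FALSE))
}
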