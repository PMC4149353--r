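#' Directed molecular interaction networks
#'
#' Wraps a directed gene graph (igraph) together with its annotated edge
#' table (`effect`, `mechanism`) and optional node roles. Parallel duplicate
#' edges (same source, target, mechanism) are not allowed; build the edge
#' table with [read_edge_list()] or [simulate_network()] which enforce this.
#'
#' @param edges data frame with columns `source`, `target`, `effect`,
#'   `mechanism`.
#' @param nodes optional character vector of node ids; defaults to all edge
#'   endpoints. Isolated nodes can be included by listing them here.
#' @param roles optional data frame with columns `gene`, `role`,
#'   `blood_expressed` (see [read_node_roles()]).
#' @return An object of class `interaction_network` with elements `graph`
#'   (igraph), `edges`, `nodes`, `roles`.
#' @export
interaction_network <- function(edges, nodes = NULL, roles = NULL) {
  stopifnot(all(c("source", "target", "effect", "mechanism") %in% names(edges)))
  key <- paste(edges$source, edges$target, edges$mechanism, sep = "\r")
  if (anyDuplicated(key)) stop("parallel duplicate edges in network")
  if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  if (!all(c(edges$source, edges$target) %in% nodes))
    stop("edge endpoint not in node set")
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  structure(list(graph = g, edges = edges, nodes = nodes, roles = roles),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "directed edges\n")
  invisible(x)
}

# 0-based CSR out-adjacency over the unique-edge graph (parallel mechanisms
# collapse to one structural edge for path computations)
network_adjacency <- function(network) {
  nodes <- network$nodes
  n <- length(nodes)
  src <- match(network$edges$source, nodes)
  tgt <- match(network$edges$target, nodes)
  keep <- !duplicated(paste(src, tgt)) & src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  o <- order(src, tgt)
  src <- src[o]; tgt <- tgt[o]
  ptr <- c(0L, cumsum(tabulate(src, nbins = n)))
  list(n = n, ptr = as.integer(ptr), idx = as.integer(tgt - 1L), nodes = nodes)
}
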