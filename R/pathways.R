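#' Identify synergistically enriched key pathways
#'
#' Three enrichment runs over the same pathway collection are compared: the
#' DEG set, the regulator set, and the combination set (enrichment of the
#' union of DEGs and regulators). A pathway is a key pathway when its
#' combination p-value is strictly lower than both single-list p-values and
#' all three pass the significance gate — synergy: the joint signature
#' concentrates on the pathway more than either evidence stream alone.
#'
#' @param deg_enrich,reg_enrich,combo_enrich data frames from [enrich()]
#'   over the same collection (mismatched set names are an error).
#' @param alpha significance gate on the raw p-values (default 0.05).
#' @return data frame sorted by `p_combo`: `set`, `p_deg`, `p_reg`,
#'   `p_combo`, `is_key`.
#' @export
identify_key_pathways <- function(deg_enrich, reg_enrich, combo_enrich,
                                  alpha = 0.05) {
  nm <- sort(deg_enrich$set)
  for (other in list(reg_enrich$set, combo_enrich$set)) {
    sd <- union(setdiff(nm, other), setdiff(other, nm))
    if (length(sd))
      stop("enrichment results cover different collections; differing sets: ",
           paste(sd, collapse = ", "))
  }
  p_deg <- deg_enrich$p[match(nm, deg_enrich$set)]
  p_reg <- reg_enrich$p[match(nm, reg_enrich$set)]
  p_combo <- combo_enrich$p[match(nm, combo_enrich$set)]
  res <- data.frame(set = nm, p_deg = p_deg, p_reg = p_reg, p_combo = p_combo,
                    stringsAsFactors = FALSE)
  res$is_key <- res$p_combo < res$p_deg & res$p_combo < res$p_reg &
    res$p_deg <= alpha & res$p_reg <= alpha & res$p_combo <= alpha
  res <- res[order(res$p_combo, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

longest_affected_run <- function(affected_flags) {
  r <- rle(affected_flags)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Affected signalling cascades on a pathway topology
#'
#' Enumerates simple directed paths that start at an affected trigger (a
#' node with role `ligand` or `receptor`), end at an affected
#' transcription factor, carry at most `max_gap` unaffected interior nodes,
#' and contain a consecutive run of at least `min_stretch` affected nodes
#' (the run may include the trigger and the transcription factor). Cycles
#' are never revisited: paths are simple.
#'
#' @param topology data frame of directed edges (`source`, `target`, plus
#'   any annotation columns).
#' @param roles data frame with columns `gene`, `role` covering the
#'   topology nodes.
#' @param affected character vector of affected genes (DEGs and
#'   regulators).
#' @param min_stretch minimum consecutive affected run (default 2).
#' @param max_gap maximum unaffected interior nodes per cascade (default 0).
#' @return list of character vectors (node paths, trigger first); empty
#'   list when no cascade qualifies.
#' @export
find_affected_cascades <- function(topology, roles, affected,
                                   min_stretch = 2, max_gap = 0) {
  if (is.null(topology) || nrow(topology) == 0L) return(list())
  g <- igraph::graph_from_data_frame(topology[, c("source", "target")],
                                     directed = TRUE)
  nodes <- igraph::V(g)$name
  role <- setNames(roles$role, roles$gene)[nodes]
  role[is.na(role)] <- "other"
  is_aff <- nodes %in% affected
  triggers <- nodes[role %in% c("ligand", "receptor") & is_aff]
  tfs <- nodes[role == "transcription-factor" & is_aff]
  if (length(triggers) == 0L || length(tfs) == 0L) return(list())
  out <- list()
  for (tr in triggers) {
    paths <- igraph::all_simple_paths(g, from = tr, to = tfs, mode = "out")
    for (p in paths) {
      pn <- igraph::V(g)$name[as.integer(p)]
      if (length(pn) < 2L) next
      if (role[pn[length(pn)]] != "transcription-factor") next
      aff <- pn %in% affected
      interior <- aff[-c(1, length(aff))]
      if (sum(!interior) > max_gap) next
      if (longest_affected_run(aff) < min_stretch) next
      out[[length(out) + 1L]] <- pn
    }
  }
  # report maximal cascades only: a qualifying path that is the suffix of a
  # longer qualifying path (its trigger sits mid-cascade) is not repeated
  if (length(out) > 1) {
    is_suffix <- vapply(seq_along(out), function(i) {
      p <- out[[i]]
      any(vapply(seq_along(out), function(j) {
        q <- out[[j]]
        j != i && length(q) > length(p) &&
          identical(q[(length(q) - length(p) + 1L):length(q)], p)
      }, TRUE))
    }, TRUE)
    out <- out[!is_suffix]
  }
  out
}

#' Reconstruct a causal network over the key-pathway topologies
#'
#' Overlays the affected genes (DEGs and regulators are both considered
#' affected in the phenotype) onto each key pathway's directed topology,
#' extracts the qualifying trigger -> cascade -> transcription-factor paths
#' ([find_affected_cascades()]), and merges the cascade edges across
#' pathways with per-edge provenance. Pathway maps may additionally carry
#' functional-module `groups` (named list of gene sets, e.g. protein
#' complexes); a group is attached as a module-group annotation when at
#' least one member is affected.
#'
#' @param key data frame from [identify_key_pathways()] (only rows with
#'   `is_key` are used).
#' @param pathways list of `pathway_map` objects (see
#'   [simulate_ontology()]); a key pathway without a topology is skipped
#'   with a warning.
#' @param degs character vector of DEGs.
#' @param regulators character vector of expression regulators.
#' @param min_stretch,max_gap passed to [find_affected_cascades()].
#' @return object of class `causal_network`: list with `nodes` (data frame
#'   `gene`, `annotation`, `pathways` — semicolon-joined provenance),
#'   `edges` (data frame `source`, `target`, `effect`, `mechanism`,
#'   `pathway`), `cascades` (list of node paths with a `pathway`
#'   attribute), and `module_groups`.
#' @export
reconstruct_causal_network <- function(key, pathways, degs, regulators,
                                       min_stretch = 2, max_gap = 0) {
  affected <- union(degs, regulators)
  by_name <- setNames(pathways, vapply(pathways, function(m) m$name, ""))
  key_names <- key$set[key$is_key]
  n_with_topology <- 0L
  edges <- list(); cascades <- list(); groups <- list()
  ann <- list(trigger = character(), `transcription-factor` = character(),
              cascade = character())
  for (nm in key_names) {
    map <- by_name[[nm]]
    if (is.null(map) || is.null(map$topology)) {
      warning("key pathway without topology skipped: ", nm)
      next
    }
    n_with_topology <- n_with_topology + 1L
    cas <- find_affected_cascades(map$topology, map$roles, affected,
                                  min_stretch = min_stretch,
                                  max_gap = max_gap)
    ekey <- paste(map$topology$source, map$topology$target)
    for (p in cas) {
      attr(p, "pathway") <- nm
      cascades[[length(cascades) + 1L]] <- p
      ann$trigger <- union(ann$trigger, p[1])
      ann$`transcription-factor` <- union(ann$`transcription-factor`,
                                          p[length(p)])
      if (length(p) > 2)
        ann$cascade <- union(ann$cascade, p[-c(1, length(p))])
      idx <- match(paste(p[-length(p)], p[-1]), ekey)
      ed <- map$topology[idx, , drop = FALSE]
      ed$pathway <- nm
      edges[[length(edges) + 1L]] <- ed
    }
    if (!is.null(map$groups)) {
      for (gn in names(map$groups)) {
        members <- map$groups[[gn]]
        if (any(members %in% affected))
          groups[[paste(nm, gn, sep = ":")]] <- members
      }
    }
  }
  if (length(edges) == 0L) {
    if (n_with_topology > 0L)
      warning("no affected trigger-to-TF cascade found; empty causal network")
    edges_df <- data.frame(source = character(), target = character(),
                           effect = character(), mechanism = character(),
                           pathway = character(), stringsAsFactors = FALSE)
  } else {
    edges_df <- do.call(rbind, edges)
    edges_df <- edges_df[!duplicated(edges_df[, c("source", "target",
                                                  "mechanism", "pathway")]), ]
    rownames(edges_df) <- NULL
  }
  node_ids <- unique(c(edges_df$source, edges_df$target,
                       unlist(groups, use.names = FALSE)))
  annotation <- vapply(node_ids, function(v) {
    a <- c(if (v %in% ann$trigger) "trigger",
           if (v %in% ann$`transcription-factor`) "transcription-factor",
           if (v %in% ann$cascade) "cascade",
           if (v %in% unlist(groups, use.names = FALSE)) "module-group")
    paste(a, collapse = ";")
  }, "")
  prov <- vapply(node_ids, function(v) {
    paste(sort(unique(edges_df$pathway[edges_df$source == v |
                                         edges_df$target == v])),
          collapse = ";")
  }, "")
  nodes_df <- data.frame(gene = node_ids, annotation = unname(annotation),
                         pathways = unname(prov), stringsAsFactors = FALSE)
  structure(list(nodes = nodes_df, edges = edges_df, cascades = cascades,
                 module_groups = groups),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat("causal_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      length(x$cascades), "cascades,", length(x$module_groups),
      "module groups\n")
  invisible(x)
}

#' Write a causal network as node/edge TSVs
#'
#' @param cn a `causal_network`.
#' @param prefix output path prefix; writes `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv`.
#' @export
write_causal_network <- function(cn, prefix) {
  stopifnot(inherits(cn, "causal_network"))
  write.table(cn$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cn$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
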