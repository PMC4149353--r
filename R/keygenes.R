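evidence_names <- c("is_deg", "is_regulator", "in_enriched_go_process",
                    "in_enriched_go_function", "on_enriched_pathway",
                    "on_enriched_process_network",
                    "on_enriched_toxicity_network", "on_key_pathway",
                    "on_causal_network", "blood_expressed")

#' Ten-criterion evidence flags for a gene
#'
#' One boolean per evidence category: 1) differentially expressed; 2)
#' expression regulator (direct or remote); 3) annotated with a GO
#' biological-process term enriched in the DEG list; 4) annotated with an
#' enriched GO molecular-function term; 5) on an enriched pathway map; 6) on
#' an enriched process network; 7) on an enriched toxicity network; 8) on a
#' key pathway map; 9) on the reconstructed causal network; 10) expressed in
#' whole blood.
#'
#' @param is_deg,is_regulator,in_enriched_go_process,in_enriched_go_function,on_enriched_pathway,on_enriched_process_network,on_enriched_toxicity_network,on_key_pathway,on_causal_network,blood_expressed
#'   logicals, default `FALSE`.
#' @return named logical vector of class `evidence_flags`.
#' @export
evidence_flags <- function(is_deg = FALSE, is_regulator = FALSE,
                           in_enriched_go_process = FALSE,
                           in_enriched_go_function = FALSE,
                           on_enriched_pathway = FALSE,
                           on_enriched_process_network = FALSE,
                           on_enriched_toxicity_network = FALSE,
                           on_key_pathway = FALSE,
                           on_causal_network = FALSE,
                           blood_expressed = FALSE) {
  flags <- c(is_deg = is_deg, is_regulator = is_regulator,
             in_enriched_go_process = in_enriched_go_process,
             in_enriched_go_function = in_enriched_go_function,
             on_enriched_pathway = on_enriched_pathway,
             on_enriched_process_network = on_enriched_process_network,
             on_enriched_toxicity_network = on_enriched_toxicity_network,
             on_key_pathway = on_key_pathway,
             on_causal_network = on_causal_network,
             blood_expressed = blood_expressed)
  stopifnot(is.logical(flags), !anyNA(flags))
  structure(flags, class = "evidence_flags")
}

#' Key-gene score
#'
#' Each satisfied evidence criterion contributes one point, so the score is
#' an integer between 0 (no criterion met) and 10 (all ten met). Genes with
#' high scores are regarded as key genes; blood-expressed high scorers are
#' biomarker candidates.
#'
#' @param flags an [evidence_flags] vector.
#' @return integer total in `[0, 10]`.
#' @export
score_gene <- function(flags) {
  stopifnot(inherits(flags, "evidence_flags"), length(flags) == 10L)
  sum(flags)
}

membership_of_enriched <- function(genes, enrichment, collection,
                                   alpha = 0.05) {
  hits <- enriched_sets(enrichment, alpha = alpha)
  if (length(hits) == 0L) return(rep(FALSE, length(genes)))
  members <- unique(unlist(collection$sets[hits], use.names = FALSE))
  genes %in% members
}

#' Collect evidence flags for genes from pipeline artifacts
#'
#' Derives the ten [evidence_flags] criteria for each gene purely from
#' upstream stage outputs. Ontology-dependent criteria (GO process, GO
#' function, pathway map, process network, toxicity network) each need an
#' `list(result = <enrich() output>, collection = <gene_sets>)` entry in
#' `artifacts$enrichments` under the names `go_process`, `go_function`,
#' `pathway`, `process_network`, `toxicity_network`; a missing entry scores
#' 0 for its flag and is logged as unavailable, so totals are only
#' comparable within one artifact configuration.
#'
#' @param genes character vector of genes to score.
#' @param artifacts list with (any of) `degs` (a `deg_list` or character
#'   vector), `regulators` (character), `enrichments` (see above),
#'   `key_pathways` (data frame from [identify_key_pathways()]),
#'   `pathway_collection` (the [gene_sets] behind `key_pathways`, for
#'   membership), `causal` (a `causal_network`), `blood` (character).
#' @param alpha significance level for the enrichment-membership criteria.
#' @return data frame: `gene`, the ten flag columns, `total`, `direction`
#'   (`up`/`down`/`none`, from `artifacts$degs` when it is a `deg_list`).
#' @export
collect_evidence <- function(genes, artifacts, alpha = 0.05) {
  n <- length(genes)
  flags <- matrix(FALSE, nrow = n, ncol = 10,
                  dimnames = list(NULL, evidence_names))
  degs <- artifacts$degs
  direction <- rep("none", n)
  if (!is.null(degs)) {
    if (inherits(degs, "deg_list")) {
      flags[, "is_deg"] <- genes %in% c(degs$up, degs$down)
      direction[genes %in% degs$up] <- "up"
      direction[genes %in% degs$down] <- "down"
    } else flags[, "is_deg"] <- genes %in% degs
  } else message("evidence unavailable: degs")
  if (!is.null(artifacts$regulators))
    flags[, "is_regulator"] <- genes %in% artifacts$regulators
  else message("evidence unavailable: regulators")
  slots <- c(go_process = "in_enriched_go_process",
             go_function = "in_enriched_go_function",
             pathway = "on_enriched_pathway",
             process_network = "on_enriched_process_network",
             toxicity_network = "on_enriched_toxicity_network")
  for (s in names(slots)) {
    e <- artifacts$enrichments[[s]]
    if (is.null(e)) { message("evidence unavailable: ", s); next }
    flags[, slots[[s]]] <- membership_of_enriched(genes, e$result,
                                                  e$collection, alpha)
  }
  if (!is.null(artifacts$key_pathways) && !is.null(artifacts$pathway_collection)) {
    keys <- artifacts$key_pathways$set[artifacts$key_pathways$is_key]
    if (length(keys)) {
      members <- unique(unlist(artifacts$pathway_collection$sets[keys],
                               use.names = FALSE))
      flags[, "on_key_pathway"] <- genes %in% members
    }
  } else message("evidence unavailable: key_pathways")
  if (!is.null(artifacts$causal))
    flags[, "on_causal_network"] <- genes %in% artifacts$causal$nodes$gene
  else message("evidence unavailable: causal")
  if (!is.null(artifacts$blood))
    flags[, "blood_expressed"] <- genes %in% artifacts$blood
  else message("evidence unavailable: blood")
  out <- data.frame(gene = genes, flags, total = rowSums(flags),
                    direction = direction, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a blood-expressed biomarker panel
#'
#' Candidates must be blood-expressed and have a known direction; the top
#' `k_up` up-regulated and `k_down` down-regulated candidates are selected
#' by score (descending), then fold-change magnitude (descending), then
#' gene id (ascending) — a deterministic ranking invariant to input order.
#' If fewer candidates than requested exist the panel is short, with a
#' warning.
#'
#' @param scores data frame from [collect_evidence()] with an added
#'   `log2fc` column (or pass `log2fc`).
#' @param k_up,k_down panel sizes per direction (default 25 each).
#' @param log2fc optional numeric vector parallel to `scores$gene`.
#' @return the input rows selected for the panel, with an `in_panel_rank`
#'   column, up-candidates first.
#' @export
build_panel <- function(scores, k_up = 25, k_down = 25, log2fc = NULL) {
  if (!is.null(log2fc)) scores$log2fc <- log2fc
  if (is.null(scores$log2fc)) stop("scores need a log2fc column")
  elig <- scores[scores$blood_expressed & scores$direction %in% c("up", "down"), ,
                 drop = FALSE]
  pick <- function(dir, k) {
    d <- elig[elig$direction == dir, , drop = FALSE]
    d <- d[order(-d$total, -abs(d$log2fc), d$gene), , drop = FALSE]
    if (nrow(d) < k)
      warning("only ", nrow(d), " eligible ", dir,
              "-regulated candidate(s) for a requested ", k)
    head(d, k)
  }
  up <- pick("up", k_up)
  down <- pick("down", k_down)
  panel <- rbind(up, down)
  panel$in_panel_rank <- c(seq_len(nrow(up)), seq_len(nrow(down)))
  rownames(panel) <- NULL
  panel
}
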