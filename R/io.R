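#' Gene-set collections
#'
#' A `gene_sets` object holds a named collection of gene sets (each with a
#' free-text description) together with a gene universe. The universe
#' defaults to the union of all member genes — the background an
#' ontology-wide enrichment test is evaluated against — and can be
#' overridden with an explicitly measured universe.
#'
#' Gene identifiers are opaque, case-sensitive, whitespace-free strings; no
#' identifier mapping is performed.
#'
#' @param sets named list of character vectors (members). Names must be
#'   unique and non-empty; every set must be non-empty.
#' @param descriptions optional character vector parallel to `sets`.
#' @param universe optional character vector; defaults to the union of all
#'   members.
#' @return An object of class `gene_sets` with elements `sets`,
#'   `descriptions` and `universe`.
#' @export
gene_sets <- function(sets, descriptions = NULL, universe = NULL) {
  stopifnot(is.list(sets), length(sets) > 0)
  nm <- names(sets)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("gene sets must have unique, non-empty names")
  if (any(vapply(sets, length, 0L) == 0L))
    stop("empty gene set: ", paste(nm[vapply(sets, length, 0L) == 0L], collapse = ", "))
  sets <- lapply(sets, function(x) unique(as.character(x)))
  for (x in unlist(sets, use.names = FALSE)) check_gene_id(x)
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(sets)), nm)
  else descriptions <- setNames(as.character(descriptions), nm)
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  structure(list(sets = sets, descriptions = descriptions,
                 universe = unique(as.character(universe))),
            class = "gene_sets")
}

check_gene_id <- function(x) {
  if (!nzchar(x) || grepl("[[:space:]]", x))
    stop("invalid gene identifier: ", deparse(x))
  invisible(x)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("gene_sets collection:", length(x$sets), "sets; universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer than
#' three fields or duplicated set names are errors.
#'
#' @param path file path.
#' @param universe optional explicit universe (character vector or a path to
#'   a one-column text file); default is the union of all members.
#' @return `read_gmt()` returns a [gene_sets] object; `write_gmt()` returns
#'   `path` invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf < 3L))
    stop("GMT parse error at line ", which(nf < 3L)[1], ": fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name in GMT: ", nm[duplicated(nm)][1])
  sets <- setNames(lapply(fields, function(f) f[-(1:2)]), nm)
  desc <- setNames(vapply(fields, `[[`, "", 2L), nm)
  if (is.character(universe) && length(universe) == 1L && file.exists(universe))
    universe <- readLines(universe)
  gene_sets(sets, desc, universe)
}

#' @rdname read_gmt
#' @param collection a [gene_sets] object.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_sets"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

edge_effects <- c("activation", "inhibition", "unspecified")
edge_mechanisms <- c("transcription-regulation", "binding", "other")
node_roles <- c("ligand", "receptor", "transducer", "transcription-factor", "other")

#' Read / write directed interaction edge lists
#'
#' TSV with header `source  target  effect  mechanism`. `effect` must be one
#' of `activation`, `inhibition`, `unspecified`; `mechanism` one of
#' `transcription-regulation`, `binding`, `other`. Exact duplicate rows are
#' collapsed with a warning; the same `(source, target, mechanism)` with two
#' different effects is an error. Self-loops are kept but flagged with a
#' warning.
#'
#' @param path file path.
#' @return `read_edge_list()` returns a data frame with columns `source`,
#'   `target`, `effect`, `mechanism` (row order of first appearance).
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  need <- c("source", "target", "effect", "mechanism")
  if (!all(need %in% names(df)))
    stop("edge list must have header columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  bad <- setdiff(unique(df$effect), edge_effects)
  if (length(bad))
    stop("unknown effect token(s) ", paste(bad, collapse = ", "),
         "; accepted: ", paste(edge_effects, collapse = ", "))
  bad <- setdiff(unique(df$mechanism), edge_mechanisms)
  if (length(bad))
    stop("unknown mechanism token(s) ", paste(bad, collapse = ", "),
         "; accepted: ", paste(edge_mechanisms, collapse = ", "))
  for (x in unique(c(df$source, df$target))) check_gene_id(x)
  key <- paste(df$source, df$target, df$mechanism, sep = "\r")
  if (anyDuplicated(key)) {
    full <- paste(key, df$effect, sep = "\r")
    if (any(duplicated(key) & !duplicated(full)))
      stop("conflicting effect annotations for a (source, target, mechanism) edge")
    warning(sum(duplicated(key)), " duplicate edge record(s) collapsed")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  if (any(df$source == df$target))
    warning(sum(df$source == df$target), " self-loop edge(s) present")
  rownames(df) <- NULL
  df
}

#' @rdname read_edge_list
#' @param edges a data frame as returned by `read_edge_list()`.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges[, c("source", "target", "effect", "mechanism")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write node-role tables
#'
#' TSV with header `gene  role  blood_expressed`; `role` is one of `ligand`,
#' `receptor`, `transducer`, `transcription-factor`, `other`;
#' `blood_expressed` is TRUE/FALSE. At most one record per gene.
#'
#' @param path file path.
#' @return a data frame with columns `gene`, `role`, `blood_expressed`.
#' @export
read_node_roles <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "logical"))
  need <- c("gene", "role", "blood_expressed")
  if (!all(need %in% names(df)))
    stop("role table must have header columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  bad <- setdiff(unique(df$role), node_roles)
  if (length(bad))
    stop("unknown role token(s) ", paste(bad, collapse = ", "),
         "; accepted: ", paste(node_roles, collapse = ", "))
  if (anyDuplicated(df$gene))
    stop("duplicate role record for gene: ", df$gene[duplicated(df$gene)][1])
  df
}

#' @rdname read_node_roles
#' @param roles data frame with columns `gene`, `role`, `blood_expressed`.
#' @export
write_node_roles <- function(roles, path) {
  write.table(roles[, c("gene", "role", "blood_expressed")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-group expression matrices
#'
#' An `expression_matrix` bundles a numeric genes-by-samples matrix (log2
#' scale throughout the pipeline) with a sample-to-group design. The
#' moderated-t stage requires exactly two groups; loading tolerates any
#' number so matrices can be subset after import.
#'
#' @param values numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids).
#' @param groups named character vector mapping every sample to a group
#'   label.
#' @return An object of class `expression_matrix` with elements `values`
#'   and `groups`.
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("sample(s) missing from design: ", paste(missing, collapse = ", "))
  groups <- as.character(groups[colnames(values)])
  names(groups) <- colnames(values)
  structure(list(values = values, groups = groups), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples; groups:", paste(sort(unique(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write expression matrices
#'
#' TSV with the first column holding gene ids and remaining columns one
#' sample each. Every sample column must appear in `design`; non-numeric
#' cells are reported with their (gene, sample) coordinates.
#'
#' @param path file path.
#' @param design named character vector mapping sample id to group label.
#' @return `read_expression()` returns an [expression_matrix].
#' @export
read_expression <- function(path, design) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column plus samples")
  genes <- df[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene id: ", genes[duplicated(genes)][1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num) && !all(is.na(num) == (vals %in% c("NA", "")))) {
    bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at gene ", genes[bad[1]], ", sample ",
         colnames(vals)[bad[2]])
  }
  dimnames(num) <- list(genes, colnames(vals))
  expression_matrix(num, design)
}

#' @rdname read_expression
#' @param em an [expression_matrix].
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  chr <- matrix(sprintf("%.17g", em$values), nrow = nrow(em$values),
                dimnames = dimnames(em$values))
  df <- data.frame(gene = rownames(em$values), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
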