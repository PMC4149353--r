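#!/usr/bin/env Rscript

# Stage 6 — key-gene scoring and biomarker panel.
#
# Scores every gene on the ten evidence criteria (DEG status, regulator
# status, enriched-ontology membership, key-pathway and causal-network
# presence, blood expression) and builds the 25-up/25-down blood-expressed
# biomarker panel. The synthetic study supplies one pathway-map ontology;
# the GO / process-network / toxicity-network criteria have no collection
# here and score 0, as logged.

suppressPackageStartupMessages(library(causalpath))

study <- "results/study"; out <- "results/pipeline"

collection <- read_gmt(file.path(study, "pathways.gmt"))
gene_tab <- read.delim(file.path(out, "gene_scores.tsv"))
degs_records <- gene_tab
dl <- list(up = gene_tab$gene[gene_tab$direction == "up"],
           down = gene_tab$gene[gene_tab$direction == "down"],
           thresholds = list(fc_cut = 1.2, p_cut = NULL),
           records = gene_tab)
class(dl) <- "deg_list"
regs <- readLines(file.path(out, "regulators.txt"))
e_deg <- read.delim(file.path(out, "enrichment_degs.tsv"))
kp <- read.delim(file.path(out, "key_pathways.tsv"))
cn_nodes <- read.delim(file.path(out, "causal_network_nodes.tsv"))
blood <- readLines(file.path(study, "blood_genes.txt"))

artifacts <- list(
  degs = dl,
  regulators = regs,
  enrichments = list(pathway = list(result = e_deg, collection = collection)),
  key_pathways = kp,
  pathway_collection = collection,
  causal = structure(list(nodes = cn_nodes), class = "causal_network"),
  blood = blood)

ev <- collect_evidence(gene_tab$gene, artifacts)
ev$log2fc <- gene_tab$log2fc[match(ev$gene, gene_tab$gene)]
write.table(ev, file.path(out, "key_gene_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("key-gene score distribution:\n")
print(table(ev$total))

panel <- build_panel(ev, k_up = 25, k_down = 25)
write.table(panel, file.path(out, "biomarker_panel.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("panel: %d genes (%d up, %d down); top scores %s\n",
            nrow(panel), sum(panel$direction == "up"),
            sum(panel$direction == "down"),
            paste(head(sort(panel$total, decreasing = TRUE), 5),
                  collapse = ", ")))
print(head(panel[, c("gene", "total", "direction", "log2fc")], 10))
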