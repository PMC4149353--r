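#!/usr/bin/env Rscript

# Stage 1 — synthetic study generation.
#
# Generates the reference synthetic study: a 1000-gene two-group expression
# experiment (10 vs 10), a 1000-node/3000-edge scale-free interaction
# network with three planted regulators (20 targets each, |log2FC| = 1,
# noise SD 0.5, each with an upstream ligand->receptor->transducer chain),
# and a 20-pathway ontology containing two planted-enriched maps and one
# causal map per regulator. Everything downstream works from the files this
# stage writes; the planted truth is kept alongside for later comparison.

suppressPackageStartupMessages({
  library(causalpath)
  library(jsonlite)
})

out <- "results/study"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 101)
study <- simulate_study(cfg)

write_expression(study$expression, file.path(out, "expression.tsv"))
write.table(data.frame(sample = names(study$expression$groups),
                       group = unname(study$expression$groups)),
            file.path(out, "design.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_edge_list(study$network$edges, file.path(out, "network_edges.tsv"))
write_node_roles(study$network$roles, file.path(out, "node_roles.tsv"))
write_gmt(study$collection, file.path(out, "pathways.gmt"))
writeLines(study$truth$blood_genes, file.path(out, "blood_genes.txt"))
write_json(study$truth[c("planted_deg_up", "planted_deg_down",
                         "planted_regulators", "planted_targets", "chains",
                         "planted_enriched_pathways", "seed")],
           file.path(out, "truth.json"), auto_unbox = FALSE, pretty = TRUE)
# pathway topologies and roles, one long table each
topo <- do.call(rbind, lapply(study$maps, function(m)
  if (is.null(m$topology)) NULL else cbind(pathway = m$name, m$topology)))
write.table(topo, file.path(out, "pathway_topologies.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
proles <- do.call(rbind, lapply(study$maps, function(m)
  if (is.null(m$roles)) NULL else cbind(pathway = m$name, m$roles)))
write.table(proles, file.path(out, "pathway_roles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Synthetic study written to", out, "\n")
cat(sprintf("  %d genes x %d samples; %d network edges; %d pathways\n",
            nrow(study$expression$values), ncol(study$expression$values),
            nrow(study$network$edges), length(study$collection$sets)))
cat(sprintf("  planted: %d up, %d down, regulators %s\n",
            length(study$truth$planted_deg_up),
            length(study$truth$planted_deg_down),
            paste(study$truth$planted_regulators, collapse = ", ")))
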