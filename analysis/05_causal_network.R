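#!/usr/bin/env Rscript

# Stage 5 — causal-network reconstruction.
#
# Overlays the affected genes (DEGs and regulators) on the key-pathway
# topologies, extracts trigger -> affected-cascade -> transcription-factor
# paths, and merges them with per-edge pathway provenance.

suppressPackageStartupMessages(library(causalpath))

study <- "results/study"; out <- "results/pipeline"

topo <- read.delim(file.path(study, "pathway_topologies.tsv"),
                   colClasses = "character")
proles <- read.delim(file.path(study, "pathway_roles.tsv"))
collection <- read_gmt(file.path(study, "pathways.gmt"))
maps <- lapply(names(collection$sets), function(nm) {
  t_nm <- topo[topo$pathway == nm, -1]
  r_nm <- proles[proles$pathway == nm, -1]
  structure(list(name = nm, members = collection$sets[[nm]],
                 topology = if (nrow(t_nm)) t_nm else NULL,
                 roles = if (nrow(r_nm)) r_nm else NULL),
            class = "pathway_map")
})

kp <- read.delim(file.path(out, "key_pathways.tsv"))
degs <- c(readLines(file.path(out, "degs_up.txt")),
          readLines(file.path(out, "degs_down.txt")))
regs <- readLines(file.path(out, "regulators.txt"))

cn <- reconstruct_causal_network(kp, maps, degs, regs,
                                 min_stretch = 2, max_gap = 0)
write_causal_network(cn, file.path(out, "causal_network"))
print(cn)
for (p in cn$cascades)
  cat(sprintf("  cascade [%s]: %s\n", attr(p, "pathway"),
              paste(p, collapse = " -> ")))
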