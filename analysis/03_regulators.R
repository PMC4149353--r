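#!/usr/bin/env Rscript

# Stage 3 — topological expression regulators.
#
# Direct regulators by hypergeometric over-connectivity of out-neighbours
# with the DEG list; remote regulators (hidden nodes) by shortest-path
# traversal excess, gated on the permutation null (normal tail, BH <= 0.05)
# because the analytic traversal-unit null is anti-conservative on networks
# of this size. The combined regulator list feeds the key-pathway stage.

suppressPackageStartupMessages(library(causalpath))

study <- "results/study"; out <- "results/pipeline"

edges <- read_edge_list(file.path(study, "network_edges.tsv"))
roles <- read_node_roles(file.path(study, "node_roles.tsv"))
nw <- interaction_network(edges, roles = roles)
degs <- c(readLines(file.path(out, "degs_up.txt")),
          readLines(file.path(out, "degs_down.txt")))

direct <- direct_regulators(nw, degs)
write.table(direct, file.path(out, "regulators_direct.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("direct regulators: %d candidates, %d with BH fdr <= 0.05\n",
            nrow(direct), sum(direct$fdr <= 0.05)))

remote <- hidden_nodes(nw, degs, null = "permutation", n_perm = 200,
                       perm_seed = 202, tail = "normal")
write.table(remote, file.path(out, "regulators_remote.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("remote regulators: %d candidates, %d with BH fdr <= 0.05\n",
            nrow(remote), sum(remote$fdr <= 0.05)))

regs <- regulator_genes(direct, remote)
writeLines(regs, file.path(out, "regulators.txt"))
cat("combined regulator list:", paste(regs, collapse = ", "), "\n")
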