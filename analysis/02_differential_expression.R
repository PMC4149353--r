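#!/usr/bin/env Rscript

# Stage 2 — differential expression.
#
# Moderated t-test on the two-group matrix, DEG calling with the linear
# fold-change rule (|FC| > 1.2, no p gate — the transcript-list convention),
# and recovery diagnostics against the planted truth.

suppressPackageStartupMessages({
  library(causalpath)
  library(jsonlite)
})

study <- "results/study"; out <- "results/pipeline"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design_df <- read.delim(file.path(study, "design.tsv"))
design <- setNames(design_df$group, design_df$sample)
em <- read_expression(file.path(study, "expression.tsv"), design)

scores <- moderated_t(em)
cat(sprintf("moderated t: prior df %.1f, prior variance %.3f\n",
            attr(scores, "prior_df"), attr(scores, "prior_var")))

degs <- call_degs(scores, fc_cut = 1.2)
write.table(degs$records, file.path(out, "gene_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(degs$up, file.path(out, "degs_up.txt"))
writeLines(degs$down, file.path(out, "degs_down.txt"))
cat(sprintf("DEGs: %d up, %d down of %d genes\n",
            length(degs$up), length(degs$down), nrow(scores)))

truth <- read_json(file.path(study, "truth.json"), simplifyVector = TRUE)
ov_up <- overlap_stats(truth$planted_deg_up, degs$up, reference = "a")
ov_dn <- overlap_stats(truth$planted_deg_down, degs$down, reference = "a")
cat(sprintf("planted recovery: up %d/%d (%.1f%%), down %d/%d (%.1f%%)\n",
            ov_up$n_intersection, ov_up$n_a, ov_up$percent_of_reference,
            ov_dn$n_intersection, ov_dn$n_a, ov_dn$percent_of_reference))
write_json(list(up = ov_up, down = ov_dn),
           file.path(out, "deg_recovery.json"), auto_unbox = TRUE)
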