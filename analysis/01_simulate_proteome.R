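#!/usr/bin/env Rscript
# Stage 1: build the synthetic benchmark proteome.
#
# 20 planted motif-positive proteins (tails drawn from the reference
# partner-peptide frequency model, guaranteed to satisfy the default rules)
# plus 10 decoys per rule class, each violating exactly one rule. Writes the
# FASTA, the annotation table (localizations + GO assignments with one term
# planted at 20x odds among the positives) and the ground-truth table.

library(clampscan)

out <- "results"
dir.create(out, showWarnings = FALSE)

sim <- generate_proteome(n_positives = 20, n_decoys_per_class = 10,
                         length_range = c(100, 500), seed = 7)
assignments <- generate_term_table(
  sim$proteome$id, n_terms = 50, planted_term = "GO:9999999",
  planted_odds = 20, seed = 8,
  planted_ids = sim$truth$id[sim$truth$is_positive])
annotations <- attach_go_terms(sim$annotations, assignments)

write_fasta(sim$proteome, file.path(out, "proteome.fasta"))
write_annotation_table(annotations, file.path(out, "annotations.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("wrote %d proteins (%d planted positives, %d decoys)\n",
            nrow(sim$proteome), sum(sim$truth$is_positive),
            sum(!sim$truth$is_positive)))
print(table(sim$truth$class))
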