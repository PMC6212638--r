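#!/usr/bin/env Rscript
# Stage 2: motif model and C-terminal scan.
#
# Builds the C-terminus-anchored frequency matrix from the eight reference
# partner decapeptides, exports the logo matrix (information content per
# position), scans the stage-1 proteome with the default rules and compares
# the hit set against the planted truth.

library(clampscan)

out <- "results"
proteome <- read_fasta(file.path(out, "proteome.fasta"))
annotations <- read_annotation_table(file.path(out, "annotations.tsv"))
truth <- read.delim(file.path(out, "truth.tsv"))

# raw frequencies for the logo (conventional reading); smoothed matrix for
# log-odds scoring during the scan
tails <- dctpr_partner_peptides(include_polyD = FALSE)
stats <- information_content(build_pfm(tails, pseudocount = 0))
pfm <- build_pfm(tails, pseudocount = 0.5)
export_logo_matrix(stats, file.path(out, "logo_matrix.tsv"))
cat(sprintf("terminal-column information: %.4f bits (max %.4f)\n",
            stats$info_bits[stats$position == 0], log2(20)))

hits <- scan_proteome(proteome, annotations, motif_criteria(), pfm = pfm)
write_hits_table(hits, file.path(out, "hits.tsv"))

pred <- hits$passed[match(truth$id, hits$id)]
sens <- sum(pred & truth$is_positive) / sum(truth$is_positive)
spec <- sum(!pred & !truth$is_positive) / sum(!truth$is_positive)
cat(sprintf("hits: %d / %d proteins; sensitivity %.3f, specificity %.3f\n",
            sum(hits$passed), nrow(hits), sens, spec))
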