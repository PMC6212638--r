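#!/usr/bin/env Rscript
# Stage 3: term over-representation among the scan hits.
#
# Hypergeometric upper-tail test per term against the full scanned
# background, Benjamini-Hochberg correction, significance at p < 1e-3 and
# q < 0.01. The stage-1 generator planted one term at elevated odds among
# the positives; it should top the table.

library(clampscan)

out <- "results"
hits <- read_hits_table(file.path(out, "hits.tsv"))
annotations <- read_annotation_table(file.path(out, "annotations.tsv"))

assignments <- setNames(annotations$go_terms, annotations$id)
enr <- enrich_terms(hits$id[hits$passed], annotations$id, assignments,
                    p_cutoff = 1e-3, q_cutoff = 0.01)
write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d terms tested, %d significant\n",
            nrow(enr), sum(enr$significant)))
print(head(enr[, c("term", "K", "k", "fold", "p_value", "q_value",
                   "significant")]))
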