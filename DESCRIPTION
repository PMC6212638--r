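Package: clampscan
Title: Proteome Screening and Binding Analysis for Dicarboxylate-Clamp TPR Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies proteins carrying Hsp70/Hsp90-like acidic C termini,
    the peptide ligands of dicarboxylate-clamp tetratricopeptide-repeat (dcTPR)
    co-chaperones. Implements a rule-based C-terminal decapeptide scan
    (terminal Asp/Glu, bulky hydrophobic anchor at the penultimate position,
    acidic-residue count, basic-residue exclusion, subcellular localization
    filters), a C-terminus-anchored position frequency matrix with sequence-logo
    information content, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, assembly and export of the partner x dcTPR
    evidence network, and a one-site competition binding model with IC50
    fitting and equilibrium displacement algebra. A synthetic-data module
    generates proteomes with planted motif-positive tails and per-rule decoys,
    annotation tables with planted term enrichment, and noisy competition
    assays, so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
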