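# Shared fixtures, built in code at test time.

interactor_tails <- function() dctpr_partner_peptides(include_polyD = FALSE)

small_proteome <- function() {
  new_proteome <- getFromNamespace("new_proteome", "clampscan")
  new_proteome(
    id = c("P1", "P2", "P3"),
    description = c("ubiquitin peptidase", "", "decoy"),
    sequence = c(paste0(strrep("A", 40), "PTYSNMEEVD"),
                 paste0(strrep("G", 30), "EDASRMEEVD"),
                 paste0(strrep("S", 25), "DDDDDDDDDD"))
  )
}

write_small_annotation <- function(path) {
  writeLines(c(
    "id\tgene\tlocalization\tgo",
    "P1\tUSP19\tcytosol;nucleus\tGO:0006511",
    "P2\tHSP90AB1\tcytosol\tGO:0006457;GO:0006511",
    "P3\tDEC1\ter_lumen\t"
  ), path)
  path
}

# 20 peptides whose columns each hold every residue once: uniform pfm columns
AA_uniform_peptides <- function(len = 5L) {
  aa <- getFromNamespace("AA_STANDARD", "clampscan")
  vapply(aa, function(a) strrep(a, len), character(1), USE.NAMES = FALSE)
}

# Independent per-rule tail check used as the enumeration oracle: counts and
# membership computed directly on the residue vector, no shared code with
# passes_criteria().
oracle_tail_check <- function(tail) {
  r <- strsplit(tail, "")[[1]]
  n <- length(r)
  last5 <- r[max(1, n - 4):n]
  (r[n] %in% c("D", "E")) &&
    (n >= 2 && r[n - 1] %in% c("V", "L", "I", "F", "Y", "W")) &&
    (sum(last5 == "D") + sum(last5 == "E") >= 2) &&
    !("K" %in% last5) && !("R" %in% last5)
}
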