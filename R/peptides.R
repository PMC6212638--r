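#' Decapeptides from the C termini of dcTPR partner proteins
#'
#' The ten utmost C-terminal residues of the characterized dicarboxylate-clamp
#' TPR (dcTPR) partner proteins used throughout the package as the reference
#' motif alignment, plus the poly-aspartate negative control. The eight
#' interactor tails (everything except `polyD`) are the training alignment for
#' [build_pfm()] and the competitor peptides of the dot-blot competition
#' assays.
#'
#' @param include_polyD logical; include the poly-D negative control.
#' @return Named character vector of decapeptides.
#' @examples
#' dctpr_partner_peptides()
#' @export
dctpr_partner_peptides <- function(include_polyD = TRUE) {
  pep <- c(
    Hsp90b   = "EDASRMEEVD",
    Hsp70.1  = "GSGPTIEEVD",
    Hsp105   = "EKNSVNMDLD",
    p23      = "SDDEKMPDLE",
    Tom20    = "AQSLAEDDVE",
    DNAAF2   = "FQNSLLYDLD",
    Usp19    = "PTYSNMEEVD",
    NADSYN1  = "AEPQSLDGVD"
  )
  if (include_polyD) pep <- c(pep, polyD = "DDDDDDDDDD")
  pep
}

#' Reported competition IC50 values for dcTPR x peptide pairs
#'
#' Half-maximal inhibitory concentrations estimated from dot-blot competition
#' assays of immobilized FKBP51 and AIP probed with HRP-conjugated decapeptides
#' and competed with the corresponding free peptides. These serve as generating
#' parameters for synthetic competition series ([simulate_competition_assay()])
#' when benchmarking IC50 recovery.
#'
#' @return data.frame with columns `dctpr`, `peptide`, `ic50_uM`.
#' @export
reported_ic50_table <- function() {
  data.frame(
    dctpr = rep(c("FKBP51", "AIP"), each = 8L),
    peptide = rep(c("Hsp90b", "Usp19", "DNAAF2", "Hsp70.1",
                    "NADSYN1", "Hsp105", "Tom20", "p23"), 2L),
    ic50_uM = c(16, 19, 25, 26, 28, 40, 183, 291,
                18,  9,  8,  7, 18,  6,  62,  47),
    stringsAsFactors = FALSE
  )
}

# 20-letter amino-acid alphabet, alphabetical; ambiguity letters kept separate.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O")

#' Controlled vocabulary of subcellular localization tags
#'
#' @return Character vector of the accepted localization tags.
#' @export
localization_vocabulary <- function() {
  c("cytosol", "nucleus", "extracellular", "er_lumen", "mito_matrix",
    "membrane_cterm_out", "membrane_cterm_in", "secreted", "unknown")
}
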