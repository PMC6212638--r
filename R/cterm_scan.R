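#' Rule set for the C-terminal motif scan
#'
#' Encodes the structural criteria for a Hsp70/Hsp90-like dicarboxylate-clamp
#' ligand tail as explicit parameters: a terminal Asp/Glu, a bulky hydrophobic
#' residue at the penultimate (-1) position, at least `min_acidic` acidic
#' residues within the last `acidic_window` positions, no Lys/Arg within the
#' last `basic_window` positions, and exclusion of localizations incompatible
#' with meeting cytosolic dcTPR proteins. The basic- and acidic-residue rules
#' apply to the last five residues by default: those positions form most of
#' the contacts in the clamp groove, and the reference ligands themselves
#' (e.g. tails of Hsp90beta, Hsp105, p23) carry Lys/Arg further upstream in
#' the decapeptide.
#'
#' @param cterm_window Tail length scanned (default 10).
#' @param terminal_residues Allowed final residues (default D, E).
#' @param minus1_hydrophobic Allowed residues at position -1
#'   (default V, L, I, F, Y, W).
#' @param min_acidic Minimum count of D/E within `acidic_window` (default 2).
#' @param acidic_window Window (from the C terminus) for the acidic count
#'   (default 5).
#' @param forbidden_basic Residues disallowed within `basic_window`
#'   (default K, R).
#' @param basic_window Window for the basic-residue exclusion (default 5).
#' @param excluded_localizations Localization tags that disqualify a protein.
#' @return A list of class `motif_criteria`.
#' @export
motif_criteria <- function(cterm_window = 10L,
                           terminal_residues = c("D", "E"),
                           minus1_hydrophobic = c("V", "L", "I", "F", "Y", "W"),
                           min_acidic = 2L,
                           acidic_window = 5L,
                           forbidden_basic = c("K", "R"),
                           basic_window = 5L,
                           excluded_localizations = c(
                             "extracellular", "secreted", "er_lumen",
                             "mito_matrix", "membrane_cterm_out")) {
  stopifnot(acidic_window <= cterm_window,
            basic_window <= cterm_window,
            min_acidic >= 1L)
  structure(
    list(cterm_window = as.integer(cterm_window),
         terminal_residues = terminal_residues,
         minus1_hydrophobic = minus1_hydrophobic,
         min_acidic = as.integer(min_acidic),
         acidic_window = as.integer(acidic_window),
         forbidden_basic = forbidden_basic,
         basic_window = as.integer(basic_window),
         excluded_localizations = excluded_localizations),
    class = "motif_criteria"
  )
}

scan_flag_names <- function() {
  c("terminal_ok", "minus1_ok", "acidic_ok", "basic_ok", "ambiguous",
    "localization_ok")
}

#' Extract the C-terminal tail of a protein
#'
#' Returns the last `window` residues. Sequences shorter than the window are
#' returned whole and flagged short; they are still evaluated on what exists.
#'
#' @param sequence Amino-acid sequence (or a one-row proteome record).
#' @param window Tail length (default 10).
#' @return List with `tail` (character) and `short` (logical).
#' @export
extract_cterm <- function(sequence, window = 10L) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence
  stopifnot(window >= 1L)
  n <- nchar(sequence)
  if (any(n == 0L)) stop("empty sequence")
  tail_ <- substring(sequence, pmax(1L, n - window + 1L), n)
  list(tail = tail_, short = n < window)
}

#' Evaluate the motif criteria on one C-terminal tail
#'
#' Applies the sequence-level rules to a tail peptide. Any ambiguity letter
#' (X, B, Z, U, O) within the tail fails closed: the verdict is FALSE and the
#' `ambiguous` flag is set. The verdict is the conjunction of the sequence
#' rules; localization is judged separately by [scan_proteome()].
#'
#' @param tail Tail peptide (possibly shorter than the nominal window).
#' @param criteria A [motif_criteria()] object.
#' @return Named list: `terminal_ok`, `minus1_ok`, `acidic_ok`, `basic_ok`,
#'   `ambiguous`, `short`, `passed`.
#' @export
passes_criteria <- function(tail, criteria = motif_criteria()) {
  if (!nzchar(tail)) stop("empty tail")
  res <- strsplit(toupper(tail), "")[[1]]
  n <- length(res)
  ambiguous <- any(res %in% AA_AMBIGUOUS)
  last_k <- function(k) res[seq.int(max(1L, n - k + 1L), n)]
  terminal_ok <- res[n] %in% criteria$terminal_residues
  minus1_ok <- n >= 2L && res[n - 1L] %in% criteria$minus1_hydrophobic
  acidic_ok <- sum(last_k(criteria$acidic_window) %in% c("D", "E")) >=
    criteria$min_acidic
  basic_ok <- !any(last_k(criteria$basic_window) %in% criteria$forbidden_basic)
  list(terminal_ok = terminal_ok,
       minus1_ok = minus1_ok,
       acidic_ok = acidic_ok,
       basic_ok = basic_ok,
       ambiguous = ambiguous,
       short = n < criteria$cterm_window,
       passed = terminal_ok && minus1_ok && acidic_ok && basic_ok && !ambiguous)
}

#' Scan a proteome for Hsp70/Hsp90-like C termini
#'
#' Applies [passes_criteria()] to the tail of every record and combines the
#' sequence verdict with the localization exclusion. Proteins whose
#' localization is only `unknown` are retained but flagged for review
#' (`review = TRUE`), mirroring a manual-inspection step rather than silently
#' dropping them. Output rows are ordered by id; scanning involves no
#' randomness.
#'
#' @param proteome Proteome `data.frame` from [read_fasta()] or
#'   [generate_proteome()].
#' @param annotations Optional annotation table from
#'   [read_annotation_table()]; ids absent from it get localization
#'   `unknown`. A count of unmatched ids is reported as a warning.
#' @param criteria A [motif_criteria()] object.
#' @param pfm Optional `pfm`; when given, full-length tails are scored with
#'   [score_peptide()] (informational only).
#' @return data.frame of class `scan_hits`: `id`, `gene`, `tail`, the rule
#'   flags, `short`, `review`, `passed`, `score_bits`.
#' @export
scan_proteome <- function(proteome, annotations = NULL,
                          criteria = motif_criteria(), pfm = NULL) {
  if (nrow(proteome) == 0L) {
    out <- data.frame(id = character(), gene = character(), tail = character(),
                      terminal_ok = logical(), minus1_ok = logical(),
                      acidic_ok = logical(), basic_ok = logical(),
                      ambiguous = logical(), localization_ok = logical(),
                      short = logical(), review = logical(),
                      passed = logical(), score_bits = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("scan_hits", "data.frame")
    return(out)
  }
  loc <- rep(list("unknown"), nrow(proteome))
  gene <- rep("", nrow(proteome))
  if (!is.null(annotations)) {
    idx <- match(proteome$id, annotations$id)
    unmatched <- sum(is.na(idx))
    if (unmatched > 0L) {
      warning(unmatched, " proteome id(s) missing from the annotation table; ",
              "treated as localization 'unknown'")
    }
    hit <- !is.na(idx)
    loc[hit] <- annotations$localization[idx[hit]]
    gene[hit] <- annotations$gene[idx[hit]]
  }
  tails <- extract_cterm(proteome$sequence, criteria$cterm_window)
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    fl <- passes_criteria(tails$tail[i], criteria)
    loc_i <- loc[[i]]
    localization_ok <- !any(loc_i %in% criteria$excluded_localizations)
    review <- identical(loc_i, "unknown") || all(loc_i == "unknown")
    score <- NA_real_
    if (!is.null(pfm) && !fl$ambiguous && !fl$short &&
        nchar(tails$tail[i]) == pfm$window) {
      score <- score_peptide(pfm, tails$tail[i])
    }
    data.frame(id = proteome$id[i], gene = gene[i], tail = tails$tail[i],
               terminal_ok = fl$terminal_ok, minus1_ok = fl$minus1_ok,
               acidic_ok = fl$acidic_ok, basic_ok = fl$basic_ok,
               ambiguous = fl$ambiguous, localization_ok = localization_ok,
               short = fl$short, review = review,
               passed = fl$passed && localization_ok,
               score_bits = score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scan_hits", "data.frame")
  out
}

#' Collapse isoform-level hits to one representative per gene
#'
#' Keeps, per gene, the longest passing isoform; ties are broken by the
#' lexicographically smaller id. Genes without a passing isoform are absent
#' from the output. Hits with no gene symbol are kept as their own
#' representatives.
#'
#' @param hits Hit table from [scan_proteome()].
#' @param proteome The proteome the hits came from (for sequence lengths).
#' @return List with `hits` (the collapsed table) and `collapsed` (named list
#'   of ids dropped per kept representative).
#' @export
collapse_isoforms <- function(hits, proteome) {
  passing <- hits[hits$passed, , drop = FALSE]
  if (nrow(passing) == 0L) {
    return(list(hits = passing, collapsed = list()))
  }
  len <- nchar(proteome$sequence)[match(passing$id, proteome$id)]
  key <- ifelse(nzchar(passing$gene), passing$gene,
                paste0(".id:", passing$id))
  keep <- logical(nrow(passing))
  collapsed <- list()
  for (g in unique(key)) {
    members <- which(key == g)
    ord <- members[order(-len[members], passing$id[members])]
    keep[ord[1L]] <- TRUE
    if (length(ord) > 1L) {
      collapsed[[passing$id[ord[1L]]]] <- passing$id[ord[-1L]]
    }
  }
  out <- passing[keep, , drop = FALSE]
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  list(hits = out, collapsed = collapsed)
}
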