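#' Build a C-terminus-anchored position frequency matrix
#'
#' Tallies residues of a set of equal-length C-terminal peptides into a 20 x L
#' count matrix and converts counts (plus a pseudocount) to per-position
#' frequencies. Alignment is right-anchored: position 0 is the utmost
#' C-terminal residue, positions run -(L-1) ... 0.
#'
#' @param peptides Character vector of equal-length peptides over the 20
#'   standard residues.
#' @param pseudocount Non-negative number added to every cell before
#'   normalization (default 0.5, Laplace-style, so log-odds stay finite).
#' @return An object of class `pfm`: list with `window`, `counts` (20 x L),
#'   `frequencies` (20 x L, columns sum to 1), `pseudocount`, `n_sequences`,
#'   `positions` (integer vector, -(L-1)..0).
#' @export
build_pfm <- function(peptides, pseudocount = 0.5) {
  if (length(peptides) < 1L) stop("need at least one peptide")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  L <- unique(nchar(peptides))
  if (length(L) != 1L) stop("peptides must all have the same length")
  mat <- do.call(rbind, strsplit(toupper(peptides), ""))
  bad <- setdiff(unique(as.vector(mat)), AA_STANDARD)
  if (length(bad)) {
    stop("non-standard residue(s) in peptides: ", paste(bad, collapse = ", "))
  }
  counts <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = AA_STANDARD))
    as.numeric(tab)
  }, numeric(20L))
  counts <- matrix(counts, nrow = 20L, ncol = L,
                   dimnames = list(AA_STANDARD, as.character(-(L - 1L):0L)))
  freqs <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), "/")
  structure(
    list(window = L, counts = counts, frequencies = freqs,
         pseudocount = pseudocount, n_sequences = length(peptides),
         positions = -(L - 1L):0L),
    class = "pfm"
  )
}

#' Per-position information content and logo letter heights
#'
#' Computes, for every column of a position frequency matrix, the Shannon
#' entropy (bits, with 0 log 0 := 0), the information content
#' `info = log2(20) - H - e`, and letter heights `freq * info`. The optional
#' small-sample correction is `e = (1/ln 2) * (s - 1) / (2 n)` with `s = 20`;
#' information is floored at 0.
#'
#' @param pfm A `pfm` from [build_pfm()].
#' @param background Residue background distribution (named numeric over the
#'   20 residues summing to 1); used only by callers ranking against the
#'   background, retained here for interface symmetry and validated.
#' @param small_sample_correction logical; apply the correction (default
#'   FALSE, matching a naive logo reading).
#' @param n_sequences Number of sequences behind the pfm (defaults to the
#'   pfm's own count); only used by the correction.
#' @return data.frame with columns `position`, `entropy_bits`, `info_bits`,
#'   and a list-column `letter_heights` (named numeric per position).
#' @export
information_content <- function(pfm, background = uniform_background(),
                                small_sample_correction = FALSE,
                                n_sequences = pfm$n_sequences) {
  stopifnot(inherits(pfm, "pfm"))
  validate_background(background)
  correction <- if (small_sample_correction) {
    (1 / log(2)) * (20 - 1) / (2 * n_sequences)
  } else 0
  cols <- lapply(seq_along(pfm$positions), function(j) {
    f <- pfm$frequencies[, j]
    nz <- f > 0
    H <- -sum(f[nz] * log2(f[nz]))
    info <- max(0, log2(20) - H - correction)
    list(position = pfm$positions[j], entropy_bits = H, info_bits = info,
         letter_heights = f * info)
  })
  out <- data.frame(
    position = vapply(cols, `[[`, integer(1), "position"),
    entropy_bits = vapply(cols, `[[`, numeric(1), "entropy_bits"),
    info_bits = vapply(cols, `[[`, numeric(1), "info_bits")
  )
  out$letter_heights <- lapply(cols, `[[`, "letter_heights")
  out
}

#' Uniform amino-acid background (1/20 per residue)
#' @return Named numeric vector over the 20 standard residues.
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20L), AA_STANDARD)
}

validate_background <- function(background) {
  if (!all(AA_STANDARD %in% names(background))) {
    stop("background must name all 20 standard residues")
  }
  if (abs(sum(background[AA_STANDARD]) - 1) > 1e-6) {
    stop("background must sum to 1")
  }
  invisible(background)
}

#' Log-odds score of a peptide against a position frequency matrix
#'
#' `score = sum_j log2(freq_j(residue_j) / background(residue_j))` in bits.
#' Intended as a ranking aid next to the rule-based scan; the hit/miss
#' decision itself is made by [passes_criteria()].
#'
#' @param pfm A `pfm` whose window equals `nchar(peptide)`.
#' @param peptide Peptide over the standard residues.
#' @param background Background distribution (default uniform).
#' @return Numeric log-odds score in bits.
#' @export
score_peptide <- function(pfm, peptide, background = uniform_background()) {
  stopifnot(inherits(pfm, "pfm"))
  validate_background(background)
  res <- strsplit(toupper(peptide), "")[[1]]
  if (length(res) != pfm$window) {
    stop("peptide length ", length(res), " != pfm window ", pfm$window)
  }
  bad <- setdiff(res, AA_STANDARD)
  if (length(bad)) {
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  }
  f <- pfm$frequencies[cbind(match(res, rownames(pfm$frequencies)),
                             seq_along(res))]
  b <- background[res]
  if (any(f == 0 & b > 0)) return(-Inf)
  sum(log2(f / b))
}

#' Export per-position logo letter heights as TSV
#'
#' One row per position, one column per residue, heights in bits; a logo
#' renderer can consume this directly. Row heights sum to the position's
#' information content.
#'
#' @param stats Output of [information_content()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_logo_matrix <- function(stats, path) {
  heights <- do.call(rbind, lapply(stats$letter_heights, function(h) {
    as.data.frame(as.list(h[AA_STANDARD]))
  }))
  names(heights) <- AA_STANDARD
  tab <- cbind(position = stats$position, heights)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a logo matrix written by [export_logo_matrix()]
#' @param path Path to the TSV file.
#' @return data.frame with `position` plus the 20 residue height columns.
#' @export
read_logo_matrix <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}
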