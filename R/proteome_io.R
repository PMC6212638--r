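#' Read a proteome FASTA file
#'
#' Parses an amino-acid FASTA file into a proteome table. Headers are split as
#' `id[ description]` on the first whitespace. Sequences are uppercased and a
#' single trailing stop symbol (`*`) is stripped. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` of class `proteome` with columns `id`, `description`
#'   and `sequence`, one row per FASTA entry in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    return(new_proteome(character(), character(), character()))
  }
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  bad <- which(!nzchar(ids) | !nzchar(seqs))
  if (length(bad)) {
    stop("malformed FASTA record(s) at index: ",
         paste(bad, collapse = ", "),
         " (empty id or empty sequence)")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  new_proteome(ids, desc, seqs)
}

new_proteome <- function(id, description, sequence) {
  out <- data.frame(id = as.character(id),
                    description = as.character(description),
                    sequence = as.character(sequence),
                    stringsAsFactors = FALSE)
  class(out) <- c("proteome", "data.frame")
  out
}

#' Write a proteome to FASTA
#'
#' Inverse of [read_fasta()]; `read_fasta(write_fasta(x, p))` returns `x`.
#'
#' @param proteome A proteome `data.frame` (`id`, `description`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(all(c("id", "sequence") %in% names(proteome)))
  aa <- Biostrings::AAStringSet(proteome$sequence)
  desc <- if ("description" %in% names(proteome)) proteome$description else ""
  names(aa) <- ifelse(nzchar(desc),
                      paste(proteome$id, desc), proteome$id)
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' Read a per-protein annotation table
#'
#' The table is TSV with header columns `id`, `gene`, `localization`
#' (semicolon-separated tags from [localization_vocabulary()]) and `go`
#' (semicolon-separated term ids). Localization tags outside the controlled
#' vocabulary are rejected; an empty localization field defaults to
#' `"unknown"`.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `id`, `gene`, and list-columns
#'   `localization` and `go_terms` (character vectors per protein).
#' @export
read_annotation_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "gene", "localization", "go")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  }
  split_field <- function(x) {
    lapply(strsplit(x, ";", fixed = TRUE),
           function(v) v[nzchar(v)])
  }
  loc <- split_field(tab$localization)
  loc <- lapply(loc, function(v) if (length(v) == 0L) "unknown" else v)
  bad <- setdiff(unique(unlist(loc)), localization_vocabulary())
  if (length(bad)) {
    stop("unknown localization tag(s): ", paste(bad, collapse = ", "))
  }
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup)) {
    stop("duplicate annotation id(s): ", paste(unique(dup), collapse = ", "))
  }
  out <- data.frame(id = tab$id, gene = tab$gene, stringsAsFactors = FALSE)
  out$localization <- loc
  out$go_terms <- split_field(tab$go)
  out
}

#' Write an annotation table
#'
#' Inverse of [read_annotation_table()].
#'
#' @param annotations Annotation `data.frame` (`id`, `gene`, list-columns
#'   `localization`, `go_terms`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  tab <- data.frame(
    id = annotations$id,
    gene = annotations$gene,
    localization = vapply(annotations$localization, paste,
                          character(1), collapse = ";"),
    go = vapply(annotations$go_terms, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a scan hit table to TSV
#'
#' One row per scanned protein with the per-rule boolean columns and the
#' overall verdict, ordered by protein id for deterministic output.
#'
#' @param hits Hit table from [scan_proteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  hits <- hits[order(hits$id), , drop = FALSE]
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a scan hit table written by [write_hits_table()]
#'
#' @param path Path to the TSV file.
#' @return Hit table `data.frame` with logical rule columns restored.
#' @export
read_hits_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in intersect(names(tab), c(scan_flag_names(), "short", "review",
                                      "passed"))) {
    tab[[col]] <- as.logical(tab[[col]])
  }
  tab
}
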