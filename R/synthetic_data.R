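#' Decoy classes produced by the synthetic proteome generator
#'
#' Five per-rule decoy classes (each violates exactly the named rule and
#' satisfies all others) plus a random-background class (uniform tails,
#' rejection-sampled so they never pass the sequence rules).
#'
#' @return Character vector of class labels.
#' @export
decoy_classes <- function() {
  c("no_terminal_DE", "no_minus1_hydrophobic", "too_few_acidic",
    "basic_in_window", "excluded_localization", "random_background")
}

# non-acidic, non-basic, non-(-1)-hydrophobic residues: safe filler for
# constrained tail positions
.neutral_res <- c("A", "G", "S", "T", "N", "Q", "P", "H", "M", "C")

sample_tail_from_pfm <- function(pfm) {
  paste(vapply(seq_len(pfm$window), function(j) {
    sample(rownames(pfm$frequencies), 1L, prob = pfm$frequencies[, j])
  }, character(1)), collapse = "")
}

# Build one tail of the requested class and assert its rule signature.
# Constructive mutation of a passing PFM-sampled tail, with retries; errors
# if the class signature cannot be realized under `criteria`.
make_class_tail <- function(class, pfm, criteria, max_tries = 200L) {
  W <- criteria$cterm_window
  for (try in seq_len(max_tries)) {
    res <- strsplit(sample_tail_from_pfm(pfm), "")[[1]]
    # coerce to a passing tail first
    res[W] <- sample(criteria$terminal_residues, 1L)
    res[W - 1L] <- sample(criteria$minus1_hydrophobic, 1L)
    aw <- seq.int(W - criteria$acidic_window + 1L, W)
    bw <- seq.int(W - criteria$basic_window + 1L, W)
    res[bw][res[bw] %in% criteria$forbidden_basic] <-
      sample(.neutral_res, sum(res[bw] %in% criteria$forbidden_basic),
             replace = TRUE)
    free <- setdiff(aw, c(W, W - 1L))
    while (sum(res[aw] %in% c("D", "E")) < criteria$min_acidic) {
      j <- free[!(res[free] %in% c("D", "E"))][1L]
      res[j] <- sample(c("D", "E"), 1L)
    }
    if (class %in% c("positive", "excluded_localization")) {
      # already passing by construction
    } else if (class == "no_terminal_DE") {
      # ensure the acidic count survives losing the terminal residue
      while (sum(res[setdiff(aw, W)] %in% c("D", "E")) < criteria$min_acidic) {
        j <- free[!(res[free] %in% c("D", "E"))][1L]
        res[j] <- sample(c("D", "E"), 1L)
      }
      res[W] <- sample(.neutral_res, 1L)
    } else if (class == "no_minus1_hydrophobic") {
      res[W - 1L] <- sample(.neutral_res, 1L)
    } else if (class == "too_few_acidic") {
      res[free] <- sample(.neutral_res, length(free), replace = TRUE)
      # keep exactly the terminal acid below the required count
      if (criteria$min_acidic <= 1L) next
    } else if (class == "basic_in_window") {
      # keep enough acids outside the basified position
      j <- sample(free, 1L)
      others <- setdiff(free, j)
      while (sum(res[setdiff(aw, j)] %in% c("D", "E")) < criteria$min_acidic &&
             any(!(res[others] %in% c("D", "E")))) {
        k <- others[!(res[others] %in% c("D", "E"))][1L]
        res[k] <- sample(c("D", "E"), 1L)
      }
      res[j] <- sample(criteria$forbidden_basic, 1L)
    } else if (class == "random_background") {
      res <- sample(AA_STANDARD, W, replace = TRUE)
    } else {
      stop("unknown tail class: ", class)
    }
    tail_ <- paste(res, collapse = "")
    fl <- passes_criteria(tail_, criteria)
    want_pass <- class %in% c("positive", "excluded_localization")
    expected_fail <- switch(class,
      no_terminal_DE = "terminal_ok",
      no_minus1_hydrophobic = "minus1_ok",
      too_few_acidic = "acidic_ok",
      basic_in_window = "basic_ok",
      NA_character_)
    ok <- if (want_pass) {
      fl$passed
    } else if (class == "random_background") {
      !fl$passed
    } else {
      !fl[[expected_fail]] &&
        all(unlist(fl[setdiff(c("terminal_ok", "minus1_ok", "acidic_ok",
                                "basic_ok"), expected_fail)])) &&
        !fl$ambiguous
    }
    if (ok) return(tail_)
  }
  stop("could not construct a '", class, "' tail under the given criteria")
}

#' Generate a synthetic proteome with planted motif-positive tails
#'
#' Emulates a proteome scan benchmark: `n_positives` proteins whose
#' C-terminal decapeptides are sampled from the reference partner-peptide
#' frequency matrix and are guaranteed to satisfy the default motif rules,
#' plus per-rule decoy classes that each violate exactly one rule
#' ([decoy_classes()]). Body residues are sampled from `background`.
#' Reproducible: the same seed gives a byte-identical proteome.
#'
#' @param n_positives Number of planted positives.
#' @param n_decoys_per_class Decoys per class.
#' @param length_range Integer range of protein lengths (default 100-500).
#' @param seed Integer seed (required).
#' @param classes Decoy classes to generate; defaults to the five per-rule
#'   classes. Add `"random_background"` for unstructured negatives.
#' @param criteria Motif rules the positives must satisfy
#'   (default [motif_criteria()]).
#' @param background Residue distribution for body residues (default
#'   uniform).
#' @return List with `proteome` (data.frame `id`, `description`,
#'   `sequence`), `annotations` (localization + gene, empty GO), and `truth`
#'   (data.frame `id`, `class`, `is_positive`).
#' @export
generate_proteome <- function(n_positives, n_decoys_per_class,
                              length_range = c(100L, 500L), seed,
                              classes = setdiff(decoy_classes(),
                                                "random_background"),
                              criteria = motif_criteria(),
                              background = uniform_background()) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_positives >= 0, n_decoys_per_class >= 0,
            length(length_range) == 2L)
  if (length_range[1] < criteria$cterm_window) {
    stop("length_range must not be shorter than the scan window")
  }
  bad <- setdiff(classes, decoy_classes())
  if (length(bad)) stop("unknown decoy class(es): ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  pfm <- build_pfm(dctpr_partner_peptides(include_polyD = FALSE),
                   pseudocount = 0.5)
  plan <- c(rep("positive", n_positives),
            rep(classes, each = n_decoys_per_class))
  n <- length(plan)
  if (n == 0L) {
    ann <- data.frame(id = character(), gene = character(),
                      stringsAsFactors = FALSE)
    ann$localization <- list()
    ann$go_terms <- list()
    return(list(proteome = new_proteome(character(), character(),
                                        character()),
                annotations = ann,
                truth = data.frame(id = character(), class = character(),
                                   is_positive = logical(),
                                   stringsAsFactors = FALSE)))
  }
  ids <- sprintf("SYN%04d", seq_len(n))
  excluded <- criteria$excluded_localizations
  recs <- lapply(seq_len(n), function(i) {
    cls <- plan[i]
    len <- sample(seq.int(length_range[1], length_range[2]), 1L)
    body <- paste(sample(AA_STANDARD, len - criteria$cterm_window,
                         replace = TRUE, prob = background[AA_STANDARD]),
                  collapse = "")
    tail_ <- make_class_tail(cls, pfm, criteria)
    loc <- switch(cls,
      positive = list(sample(list("cytosol", "nucleus",
                                  c("cytosol", "nucleus")), 1L)[[1]]),
      excluded_localization = list(sample(excluded, 1L)),
      list("cytosol"))[[1]]
    list(sequence = paste0(body, tail_), localization = loc, class = cls)
  })
  proteome <- new_proteome(
    ids, paste("synthetic", plan, "protein"),
    vapply(recs, `[[`, character(1), "sequence"))
  annotations <- data.frame(id = ids, gene = sprintf("GENE%04d", seq_len(n)),
                            stringsAsFactors = FALSE)
  annotations$localization <- lapply(recs, `[[`, "localization")
  annotations$go_terms <- rep(list(character()), n)
  truth <- data.frame(id = ids, class = plan,
                      is_positive = plan == "positive",
                      stringsAsFactors = FALSE)
  list(proteome = proteome, annotations = annotations, truth = truth)
}

#' Generate a term-assignment table with one planted enriched term
#'
#' Background terms are assigned to every id independently at `base_rate`.
#' The planted term is assigned at `base_rate` to all ids and at
#' `min(1, base_rate * planted_odds)` to `planted_ids`, so `planted_odds = 1`
#' plants no enrichment.
#'
#' @param ids Character vector of protein ids.
#' @param n_terms Number of background terms.
#' @param planted_term Term id for the planted term; must not collide with
#'   the generated background term ids.
#' @param planted_odds Odds multiplier (>= 1) applied to `planted_ids`.
#' @param seed Integer seed (required).
#' @param planted_ids Ids receiving the planted term at elevated odds.
#' @param base_rate Per-term assignment probability (default 0.05).
#' @return Named list mapping id -> character vector of term ids.
#' @export
generate_term_table <- function(ids, n_terms = 50L,
                                planted_term = "GO:9999999",
                                planted_odds = 1, seed,
                                planted_ids = character(),
                                base_rate = 0.05) {
  if (missing(seed)) stop("seed is required")
  stopifnot(planted_odds >= 1, base_rate > 0, base_rate <= 1)
  if (length(ids) == 0L) return(stats::setNames(list(), character()))
  bg_terms <- sprintf("GO:%07d", seq_len(n_terms))
  if (planted_term %in% bg_terms) {
    stop("planted term id collides with a background term id: ", planted_term)
  }
  set.seed(as.integer(seed))
  p_planted <- ifelse(ids %in% planted_ids,
                      min(1, base_rate * planted_odds), base_rate)
  out <- lapply(seq_along(ids), function(i) {
    terms <- bg_terms[stats::runif(n_terms) < base_rate]
    if (stats::runif(1) < p_planted[i]) terms <- c(terms, planted_term)
    terms
  })
  stats::setNames(out, ids)
}

#' Attach generated term assignments to an annotation table
#'
#' @param annotations Annotation data.frame with an `id` column.
#' @param assignments Named list from [generate_term_table()].
#' @return `annotations` with its `go_terms` list-column filled in.
#' @export
attach_go_terms <- function(annotations, assignments) {
  idx <- match(annotations$id, names(assignments))
  annotations$go_terms <- lapply(seq_along(idx), function(i) {
    if (is.na(idx[i])) character() else assignments[[idx[i]]]
  })
  annotations
}
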