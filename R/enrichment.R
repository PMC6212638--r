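#' Upper-tail hypergeometric probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated proteins when `n` are drawn without replacement
#' from a background of `N` of which `K` carry the annotation. Computed with
#' the survival function of [stats::phyper] for numerical stability.
#'
#' @param N Background size.
#' @param K Number of annotated proteins in the background.
#' @param n Hit-set size.
#' @param k Observed overlap.
#' @return Probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, K <= N, n <= N, k >= 0)
  if (k > K || k > n) {
    stop("impossible configuration: k exceeds K or n")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation in a hit set
#'
#' Hypergeometric over-representation of each term among the hits relative to
#' the background, with Benjamini-Hochberg correction across all tested
#' terms. This is a fixed-list test: the hit set is unranked. A term is
#' flagged significant when `p < p_cutoff` and `q < q_cutoff`.
#'
#' @param hit_ids Character vector of hit ids (subset of `background_ids`).
#' @param background_ids Character vector, the scanned universe.
#' @param term_assignments Named list mapping id -> character vector of term
#'   ids (e.g. the `go_terms` column of [read_annotation_table()] named by
#'   id).
#' @param p_cutoff Raw p-value cutoff (default 1e-3).
#' @param q_cutoff BH q-value cutoff (default 0.01).
#' @return data.frame with one row per term present in the background
#'   (`term`, `N`, `K`, `n`, `k`, `fold`, `p_value`, `q_value`,
#'   `significant`), sorted by p-value then term id.
#' @export
enrich_terms <- function(hit_ids, background_ids, term_assignments,
                         p_cutoff = 1e-3, q_cutoff = 0.01) {
  if (length(background_ids) == 0L) stop("empty background")
  if (!all(hit_ids %in% background_ids)) {
    stop("hit_ids must be a subset of background_ids")
  }
  terms_bg <- term_assignments[background_ids]
  terms_bg[vapply(terms_bg, is.null, logical(1))] <- list(character())
  all_terms <- sort(unique(unlist(terms_bg)))
  N <- length(background_ids)
  n <- length(hit_ids)
  in_hits <- background_ids %in% hit_ids
  rows <- lapply(all_terms, function(tm) {
    has <- vapply(terms_bg, function(v) tm %in% v, logical(1))
    K <- sum(has)
    k <- sum(has & in_hits)
    p <- hypergeom_upper_tail(N, K, n, k)
    fold <- if (n == 0L || K == 0L) NA_real_ else (k / n) / (K / N)
    data.frame(term = tm, N = N, K = K, n = n, k = k, fold = fold,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), fold = numeric(),
                      p_value = numeric())
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < p_cutoff & out$q_value < q_cutoff
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
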