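#' Evidence classes for partner x dcTPR interactions
#'
#' The closed set of evidence labels an interaction edge may carry:
#' previously confirmed dicarboxylate-clamp interactions, clamp interactions
#' established in the present screen, chaperone-interactome proteomics, and
#' interaction-database records.
#'
#' @return Character vector of the four evidence classes.
#' @export
evidence_classes <- function() {
  c("dc_clamp_prior", "dc_clamp_this_study",
    "chaperone_interactome", "interaction_database")
}

#' Assemble the partner x dcTPR evidence network
#'
#' Builds a bipartite graph between candidate partner proteins and dcTPR
#' proteins. Nodes carry a `role` attribute (`partner` or `dctpr`); partner
#' nodes present in the scan hit set are flagged `motif_positive`. Duplicate
#' (partner, dcTPR, evidence) triples collapse to a single edge; the same
#' pair may carry several edges with distinct evidence. Edges whose partner
#' is a core Hsp70/Hsp90-family chaperone are dropped by default, since those
#' interactions are ubiquitous and would obscure the novel part of the
#' network.
#'
#' @param scan_hits Hit table from [scan_proteome()] (only passing rows are
#'   used), or NULL.
#' @param dctpr_ids Character vector of dcTPR protein ids.
#' @param evidence_edges data.frame with columns `partner`, `dctpr`,
#'   `evidence`.
#' @param chaperone_ids Partner ids considered Hsp70/Hsp90-family members.
#' @param include_chaperone_edges logical; keep chaperone edges (default
#'   FALSE).
#' @return An [igraph::igraph] bipartite graph.
#' @export
assemble_network <- function(scan_hits = NULL, dctpr_ids, evidence_edges,
                             chaperone_ids = character(),
                             include_chaperone_edges = FALSE) {
  stopifnot(all(c("partner", "dctpr", "evidence") %in% names(evidence_edges)))
  bad_ev <- setdiff(unique(evidence_edges$evidence), evidence_classes())
  if (length(bad_ev)) {
    stop("unknown evidence class(es): ", paste(bad_ev, collapse = ", "))
  }
  overlap <- intersect(evidence_edges$partner, dctpr_ids)
  if (length(overlap)) {
    stop("id(s) used as both partner and dcTPR: ",
         paste(overlap, collapse = ", "))
  }
  edges <- unique(evidence_edges[, c("partner", "dctpr", "evidence")])
  if (!include_chaperone_edges) {
    edges <- edges[!(edges$partner %in% chaperone_ids), , drop = FALSE]
  }
  bad_dctpr <- setdiff(edges$dctpr, dctpr_ids)
  if (length(bad_dctpr)) {
    stop("edge(s) reference unknown dcTPR id(s): ",
         paste(unique(bad_dctpr), collapse = ", "))
  }
  partners <- sort(unique(edges$partner))
  dctprs <- sort(unique(dctpr_ids))
  hit_ids <- if (is.null(scan_hits)) character() else {
    scan_hits$id[scan_hits$passed]
  }
  nodes <- data.frame(
    name = c(partners, dctprs),
    role = c(rep("partner", length(partners)), rep("dctpr", length(dctprs))),
    motif_positive = c(partners %in% hit_ids, rep(FALSE, length(dctprs))),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$partner, edges$dctpr, edges$evidence), ,
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$partner, to = edges$dctpr,
                   evidence = edges$evidence, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  igraph::V(g)$type <- igraph::V(g)$role == "dctpr"  # bipartite marker
  g
}

#' Export an interaction graph
#'
#' Supported formats: `graphml` (lossless for node/edge attributes), `sif`
#' (`partner<TAB>evidence<TAB>dctpr` lines, one per edge) and `tsv` (edge
#' list with evidence column). Node and edge order is deterministic.
#'
#' @param graph Graph from [assemble_network()].
#' @param path Output path.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph)
  ev <- igraph::E(graph)$evidence
  if (format == "sif") {
    lines <- if (nrow(el)) paste(el[, 1], ev, el[, 2], sep = "\t") else
      character()
    writeLines(lines, path)
  } else {
    utils::write.table(
      data.frame(partner = el[, 1], dctpr = el[, 2], evidence = ev),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML interaction graph back
#' @param path Path to a GraphML file written by [export_graph()].
#' @return An [igraph::igraph].
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
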