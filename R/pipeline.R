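#' Default pipeline configuration
#'
#' A flat list of every tunable the end-to-end run uses: motif criteria,
#' synthetic proteome sizes, enrichment cutoffs, competition-assay design and
#' the master seed. The configuration round-trips through a YAML file
#' ([write_pipeline_config()] / [read_pipeline_config()]); unknown keys are
#' rejected on read.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 7L,
    n_positives = 20L,
    n_decoys_per_class = 10L,
    length_range = c(100L, 500L),
    cterm_window = 10L,
    basic_window = 5L,
    acidic_window = 5L,
    min_acidic = 2L,
    n_go_terms = 50L,
    planted_term = "GO:9999999",
    planted_odds = 20,
    go_base_rate = 0.05,
    p_cutoff = 1e-3,
    q_cutoff = 0.01,
    concentrations_uM = c(0, 0.5, 1.6, 5, 16, 50, 160, 500, 1000),
    n_reps = 3L,
    noise_sd = 5,
    assay_top = 100,
    assay_bottom = 0,
    fold_threshold = 10,
    collapse_genes = FALSE
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

criteria_from_config <- function(config) {
  motif_criteria(cterm_window = config$cterm_window,
                 basic_window = config$basic_window,
                 acidic_window = config$acidic_window,
                 min_acidic = config$min_acidic)
}

#' Run the full in-silico screen end to end
#'
#' Simulated proteome -> motif scan -> term enrichment -> evidence network,
#' plus simulated competition assays -> IC50 fits -> affinity tiers. Every
#' stage's table is written under `out_dir` together with a JSON run manifest
#' echoing the seeds and criteria, so a rerun with the same configuration
#' reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `hits`, `enrichment`, `graph`, `fits`,
#'   `tiers`, `truth` and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  criteria <- criteria_from_config(config)
  sim <- generate_proteome(config$n_positives, config$n_decoys_per_class,
                           config$length_range, seed = config$seed,
                           criteria = criteria)
  assignments <- generate_term_table(
    sim$proteome$id, n_terms = config$n_go_terms,
    planted_term = config$planted_term, planted_odds = config$planted_odds,
    seed = config$seed + 1L,
    planted_ids = sim$truth$id[sim$truth$is_positive],
    base_rate = config$go_base_rate)
  annotations <- attach_go_terms(sim$annotations, assignments)
  write_fasta(sim$proteome, file.path(out_dir, "proteome.fasta"))
  write_annotation_table(annotations, file.path(out_dir, "annotations.tsv"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pfm <- build_pfm(dctpr_partner_peptides(include_polyD = FALSE), 0.5)
  hits <- scan_proteome(sim$proteome, annotations, criteria, pfm = pfm)
  if (isTRUE(config$collapse_genes)) {
    hits_out <- collapse_isoforms(hits, sim$proteome)$hits
  } else {
    hits_out <- hits
  }
  write_hits_table(hits_out, file.path(out_dir, "hits.tsv"))
  export_logo_matrix(information_content(pfm),
                     file.path(out_dir, "logo_matrix.tsv"))

  enr <- enrich_terms(hits$id[hits$passed], sim$proteome$id, assignments,
                      p_cutoff = config$p_cutoff, q_cutoff = config$q_cutoff)
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  edges <- utils::read.delim(
    system.file("extdata", "network_edges_curated_partial.tsv",
                package = "clampscan"),
    comment.char = "#", stringsAsFactors = FALSE)
  dctpr_ids <- readLines(system.file("extdata", "dctpr_proteins.txt",
                                     package = "clampscan"))
  dctpr_ids <- dctpr_ids[!startsWith(dctpr_ids, "#") & nzchar(dctpr_ids)]
  graph <- assemble_network(NULL, dctpr_ids, edges,
                            chaperone_ids = c("Hsp90b", "Hsp70.1"))
  export_graph(graph, file.path(out_dir, "network.graphml"), "graphml")

  ic50s <- reported_ic50_table()
  fits <- do.call(rbind, lapply(seq_len(nrow(ic50s)), function(i) {
    concs <- config$concentrations_uM
    if (max(concs) < 10 * ic50s$ic50_uM[i]) {
      concs <- c(concs, 10 * ic50s$ic50_uM[i])
    }
    assay <- simulate_competition_assay(
      competition_params(config$assay_top, config$assay_bottom,
                         ic50s$ic50_uM[i]),
      concs, n_reps = config$n_reps, noise_sd = config$noise_sd,
      seed = config$seed * 100L + i,
      label = paste(ic50s$dctpr[i], ic50s$peptide[i], sep = " x "))
    fit <- fit_ic50(assay)
    data.frame(dctpr = ic50s$dctpr[i], peptide = ic50s$peptide[i],
               true_ic50_uM = ic50s$ic50_uM[i],
               ic50_uM = if (fit$converged) fit$params$ic50_uM else NA_real_,
               converged = fit$converged, stringsAsFactors = FALSE)
  }))
  tiers <- classify_affinity_tiers(fits[fits$converged, , drop = FALSE],
                                   fold_threshold = config$fold_threshold)
  utils::write.table(fits, file.path(out_dir, "ic50_fits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tiers, file.path(out_dir, "affinity_tiers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "clampscan",
    version = as.character(utils::packageVersion("clampscan")),
    seed = config$seed,
    criteria = unclass(criteria),
    config = unclass(config),
    n_proteins = nrow(sim$proteome),
    n_hits = sum(hits$passed),
    n_significant_terms = sum(enr$significant)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(hits = hits_out, enrichment = enr, graph = graph,
                 fits = fits, tiers = tiers, truth = sim$truth,
                 manifest = manifest))
}
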