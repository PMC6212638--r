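fixture_edges <- function() {
  data.frame(
    partner = c("Usp19", "Usp19", "Hsp105", "Tom20", "Tom20", "Rpn13"),
    dctpr = c("AIP", "FKBP51", "FKBP51", "Tom70", "AIP", "SGTA"),
    evidence = c("dc_clamp_this_study", "dc_clamp_this_study",
                 "dc_clamp_this_study", "dc_clamp_prior", "dc_clamp_prior",
                 "dc_clamp_prior"),
    stringsAsFactors = FALSE)
}

test_that("network assembly builds a bipartite evidence graph", {
  edges <- fixture_edges()
  g <- assemble_network(NULL, c("AIP", "FKBP51", "Tom70", "SGTA"), edges)
  expect_equal(igraph::ecount(g), 6L)
  expect_equal(igraph::vcount(g), 8L)
  expect_true(igraph::is_bipartite(g))
  expect_equal(igraph::degree(g, "Usp19"), c(Usp19 = 2))
  roles <- igraph::V(g)$role
  expect_setequal(unique(roles), c("partner", "dctpr"))
  # duplicate triples collapse to one edge
  g2 <- assemble_network(NULL, c("AIP", "FKBP51", "Tom70", "SGTA"),
                         rbind(edges, edges[1, ]))
  expect_equal(igraph::ecount(g2), 6L)
})

test_that("edges with unknown evidence or ids are rejected", {
  edges <- fixture_edges()
  edges$evidence[1] <- "hearsay"
  expect_error(assemble_network(NULL, c("AIP", "FKBP51", "Tom70", "SGTA"),
                                edges), "hearsay")
  edges <- fixture_edges()
  expect_error(assemble_network(NULL, c("AIP", "FKBP51"), edges), "Tom70")
  # an id on both sides breaks bipartiteness
  edges2 <- rbind(fixture_edges(),
                  data.frame(partner = "AIP", dctpr = "FKBP51",
                             evidence = "interaction_database"))
  expect_error(assemble_network(NULL, c("AIP", "FKBP51", "Tom70", "SGTA"),
                                edges2), "both")
})

test_that("chaperone partner edges are suppressed by default", {
  edges <- rbind(fixture_edges(),
                 data.frame(partner = "Hsp90b", dctpr = "FKBP51",
                            evidence = "dc_clamp_prior"))
  g <- assemble_network(NULL, c("AIP", "FKBP51", "Tom70", "SGTA"), edges,
                        chaperone_ids = "Hsp90b")
  expect_false("Hsp90b" %in% igraph::V(g)$name)
  g_all <- assemble_network(NULL, c("AIP", "FKBP51", "Tom70", "SGTA"), edges,
                            chaperone_ids = "Hsp90b",
                            include_chaperone_edges = TRUE)
  expect_true("Hsp90b" %in% igraph::V(g_all)$name)
})

test_that("motif-positive partners are flagged from the scan hits", {
  sim <- generate_proteome(3, 0, c(50, 80), seed = 2)
  hits <- scan_proteome(sim$proteome, sim$annotations)
  edges <- data.frame(partner = c(hits$id[1], "Other"),
                      dctpr = "FKBP51",
                      evidence = "dc_clamp_this_study")
  g <- assemble_network(hits, "FKBP51", edges)
  v <- igraph::V(g)
  expect_true(v$motif_positive[v$name == hits$id[1]])
  expect_false(v$motif_positive[v$name == "Other"])
})

test_that("graph export round-trips attributes and formats count edges", {
  g <- assemble_network(NULL, c("AIP", "FKBP51", "Tom70", "SGTA"),
                        fixture_edges())
  gm <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gm, "graphml")
  back <- read_graphml(gm)
  expect_equal(sort(igraph::V(back)$name), sort(igraph::V(g)$name))
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  eb <- igraph::as_data_frame(back, "edges")
  eg <- igraph::as_data_frame(g, "edges")
  ord <- function(d) d[order(d$from, d$to, d$evidence), ]
  expect_equal(ord(eb)$evidence, ord(eg)$evidence)
  expect_equal(igraph::V(back)$role[match(igraph::V(g)$name,
                                          igraph::V(back)$name)],
               igraph::V(g)$role)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(g, sif, "sif")
  expect_equal(length(readLines(sif)), igraph::ecount(g))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, tsv, "tsv")
  expect_equal(nrow(utils::read.delim(tsv)), igraph::ecount(g))

  # empty graph still exports a valid document
  g0 <- assemble_network(NULL, "FKBP51",
                         fixture_edges()[0, , drop = FALSE])
  export_graph(g0, gm, "graphml")
  expect_equal(igraph::ecount(read_graphml(gm)), 0L)
  export_graph(g0, sif, "sif")
  expect_equal(length(readLines(sif)), 0L)
})
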