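test_that("C-terminal extraction returns the tail window and flags short", {
  got <- extract_cterm("AAAEDASRMEEVD", 10)
  expect_equal(got$tail, "EDASRMEEVD")
  expect_false(got$short)

  short <- extract_cterm("MEEVD", 10)
  expect_equal(short$tail, "MEEVD")
  expect_true(short$short)

  expect_equal(extract_cterm("AAAD", 1)$tail, "D")
  expect_error(extract_cterm("", 10), "empty")
})

test_that("the reference decapeptides behave as their binding data implies", {
  # all eight interactor tails pass; note Hsp90b carries R at -5 and Hsp105
  # K at -8, both outside the 5-residue basic window
  for (p in interactor_tails()) {
    expect_true(passes_criteria(p)$passed, label = p)
  }
  # poly-D fails only at the hydrophobic anchor
  fl <- passes_criteria("DDDDDDDDDD")
  expect_false(fl$passed)
  expect_false(fl$minus1_ok)
  expect_true(fl$terminal_ok && fl$acidic_ok && fl$basic_ok)

  expect_false(passes_criteria("MEEVK")$terminal_ok)
})

test_that("ambiguity letters fail closed within the scanned window", {
  for (amb in c("X", "B", "Z", "U", "O")) {
    tail_ <- paste0("PTYSNM", amb, "EVD")
    fl <- passes_criteria(tail_)
    expect_true(fl$ambiguous, label = amb)
    expect_false(fl$passed, label = amb)
  }
})

test_that("restricted-alphabet pentapeptide enumeration matches the
           exhaustive oracle", {
  alphabet <- c("A", "D", "E", "K", "V")
  grid <- expand.grid(rep(list(alphabet), 5), stringsAsFactors = FALSE)
  peps <- do.call(paste0, grid)
  verdict <- vapply(peps, function(p) passes_criteria(p)$passed, logical(1))
  oracle <- vapply(peps, oracle_tail_check, logical(1))
  expect_equal(length(peps), 3125L)
  expect_equal(unname(verdict), unname(oracle))
  expect_equal(sum(verdict), 112L)
})

test_that("scanning recovers exactly the planted positives and applies the
           localization exclusion", {
  sim <- generate_proteome(20, 10, c(100, 500), seed = 7)
  expect_equal(nrow(sim$proteome), 20L + 5L * 10L)
  hits <- scan_proteome(sim$proteome, sim$annotations)
  expect_setequal(hits$id[hits$passed],
                  sim$truth$id[sim$truth$is_positive])
  # localization-excluded decoys pass every sequence rule but not the scan
  excl <- sim$truth$id[sim$truth$class == "excluded_localization"]
  rows <- hits[hits$id %in% excl, ]
  expect_true(all(!rows$localization_ok))
  expect_true(all(rows$terminal_ok & rows$minus1_ok & rows$acidic_ok &
                    rows$basic_ok))
  expect_true(all(!rows$passed))

  empty <- scan_proteome(sim$proteome[0, ], sim$annotations)
  expect_equal(nrow(empty), 0L)
})

test_that("scanning is deterministic and monotone under relaxed criteria", {
  sim <- generate_proteome(10, 6, c(100, 300), seed = 19)
  h1 <- scan_proteome(sim$proteome, sim$annotations)
  h2 <- scan_proteome(sim$proteome, sim$annotations)
  expect_identical(h1, h2)

  relaxed <- motif_criteria(
    terminal_residues = c("D", "E", "N", "Q"),
    minus1_hydrophobic = c("V", "L", "I", "F", "Y", "W", "M", "A"),
    min_acidic = 1L,
    forbidden_basic = "K",
    excluded_localizations = "extracellular")
  h3 <- scan_proteome(sim$proteome, sim$annotations, relaxed)
  expect_true(all(h1$id[h1$passed] %in% h3$id[h3$passed]))
})

test_that("unannotated and unknown-localization proteins are kept but
           flagged for review", {
  prot <- small_proteome()
  ann <- data.frame(id = "P1", gene = "USP19", stringsAsFactors = FALSE)
  ann$localization <- list("cytosol")
  ann$go_terms <- list(character())
  expect_warning(hits <- scan_proteome(prot, ann),
                 "missing from the annotation")
  expect_true(all(hits$review[hits$id != "P1"]))
  expect_false(hits$review[hits$id == "P1"])
  expect_true(hits$passed[hits$id == "P1"])
  # no annotation table at all: everything is review-flagged, nothing warns
  expect_silent(hits2 <- scan_proteome(prot))
  expect_true(all(hits2$review))
})

test_that("isoform collapse keeps the longest passing isoform per gene", {
  new_proteome <- getFromNamespace("new_proteome", "clampscan")
  prot <- new_proteome(
    id = c("I1", "I2", "I3", "I4"),
    description = "",
    sequence = c(paste0(strrep("A", 490), "PTYSNMEEVD"),
                 paste0(strrep("A", 440), "PTYSNMEEVD"),
                 paste0(strrep("G", 90), "EDASRMEEVD"),
                 paste0(strrep("G", 90), "DDDDDDDDDD")))
  ann <- data.frame(id = c("I1", "I2", "I3", "I4"),
                    gene = c("USP19", "USP19", "HSP90", "NOPE"),
                    stringsAsFactors = FALSE)
  ann$localization <- rep(list("cytosol"), 4)
  ann$go_terms <- rep(list(character()), 4)
  hits <- scan_proteome(prot, ann)
  col <- collapse_isoforms(hits, prot)
  expect_setequal(col$hits$id, c("I1", "I3"))
  expect_equal(col$collapsed[["I1"]], "I2")
  # equal lengths: lexicographically smaller id wins
  prot2 <- prot
  prot2$sequence[2] <- prot2$sequence[1]
  col2 <- collapse_isoforms(scan_proteome(prot2, ann), prot2)
  expect_true("I1" %in% col2$hits$id && !("I2" %in% col2$hits$id))
  # genes with no passing isoform are absent
  expect_false("NOPE" %in% col$hits$gene)
})
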