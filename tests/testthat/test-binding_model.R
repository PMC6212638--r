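test_that("one-site competition signal obeys its defining points", {
  p <- competition_params(top = 100, bottom = 0, ic50_uM = 16)
  expect_equal(competition_signal(p, 0), 100)
  expect_equal(competition_signal(p, 16), 50)
  expect_equal(competition_signal(p, 183), 100 / (1 + 183 / 16),
               tolerance = 1e-12)
  # strictly decreasing in concentration when top > bottom
  cs <- competition_signal(p, c(0, 1, 5, 20, 100, 1000))
  expect_true(all(diff(cs) < 0))
  expect_error(competition_params(10, 20, 5))
})

test_that("assay simulation is seed-reproducible and unbiased", {
  p <- competition_params(100, 0, 16)
  concs <- c(0, 1, 10, 100)
  a0 <- simulate_competition_assay(p, concs, 3, noise_sd = 0, seed = 1)
  expect_equal(unname(a0$signals),
               matrix(rep(competition_signal(p, concs), each = 3), nrow = 3))
  a1 <- simulate_competition_assay(p, concs, 3, noise_sd = 5, seed = 1)
  a1b <- simulate_competition_assay(p, concs, 3, noise_sd = 5, seed = 1)
  expect_identical(a1$signals, a1b$signals)
  a2 <- simulate_competition_assay(p, concs, 3, noise_sd = 5, seed = 2)
  expect_false(identical(a1$signals, a2$signals))
  # means agree with the model within 3 SE over many replicates
  big <- simulate_competition_assay(p, concs, 1000, noise_sd = 5, seed = 3)
  se <- 5 / sqrt(1000)
  expect_true(all(abs(colMeans(big$signals) -
                        competition_signal(p, concs)) < 3 * se + 0.05))
  expect_error(simulate_competition_assay(p, numeric(), 3, 0, seed = 1),
               "empty")
})

test_that("assay tables round-trip through TSV", {
  a <- simulate_competition_assay(competition_params(100, 5, 30),
                                  c(0, 1, 10, 100, 1000), 3, 4, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assay_table(a, path)
  back <- read_assay_table(path, label = a$label)
  expect_equal(back$concentrations_uM, a$concentrations_uM)
  expect_equal(unname(back$signals), unname(a$signals))
})

test_that("IC50 fitting recovers noiseless parameters exactly", {
  p <- competition_params(100, 0, 16)
  concs <- c(0, 0.5, 1.6, 5, 16, 50, 160, 500, 1000)
  a <- simulate_competition_assay(p, concs, 2, noise_sd = 0, seed = 1)
  fit <- fit_ic50(a)
  expect_true(fit$converged)
  expect_equal(fit$params$ic50_uM, 16, tolerance = 1e-6)
  expect_equal(fit$params$top, 100, tolerance = 1e-6)
  expect_equal(fit$params$bottom, 0, tolerance = 1e-4)
})

test_that("fitting errors on flat data and too few concentrations", {
  flat <- structure(list(label = "", concentrations_uM = c(0, 1, 10, 100),
                         signals = matrix(50, 2, 4), seed = 1L),
                    class = "competition_assay")
  expect_error(fit_ic50(flat), "no transition")
  a <- simulate_competition_assay(competition_params(100, 0, 16),
                                  c(0, 10, 100), 3, 0, seed = 1)
  expect_error(fit_ic50(a), "4 distinct")
})

test_that("fitted IC50 matches a profiled grid-search oracle", {
  a <- simulate_competition_assay(competition_params(100, 0, 40),
                                  c(0, 0.5, 1.6, 5, 16, 50, 160, 500, 1000),
                                  3, noise_sd = 5, seed = 17)
  conc <- rep(a$concentrations_uM, each = nrow(a$signals))
  y <- as.vector(a$signals)
  # profile out (top, bottom) by linear least squares at each candidate IC50
  grid <- 10^seq(log10(0.05), log10(5000), length.out = 4000)
  rss <- vapply(grid, function(ic) {
    f <- 1 / (1 + conc / ic)
    sum(stats::lm.fit(cbind(1, f), y)$residuals^2)
  }, numeric(1))
  oracle <- grid[which.min(rss)]
  fit <- fit_ic50(a)
  expect_true(fit$converged)
  expect_equal(fit$params$ic50_uM, oracle, tolerance = 0.02)
})

test_that("IC50 fitting is scale-equivariant in concentration units", {
  a <- simulate_competition_assay(competition_params(90, 5, 25),
                                  c(0, 0.5, 2, 8, 32, 128, 512), 3,
                                  noise_sd = 3, seed = 23)
  f1 <- fit_ic50(a)
  a_nM <- a
  a_nM$concentrations_uM <- a$concentrations_uM * 1000
  f2 <- fit_ic50(a_nM)
  expect_equal(f2$params$ic50_uM / f1$params$ic50_uM, 1000,
               tolerance = 1e-6)
})

test_that("median IC50 recovery error stays under 10% at 5% noise", {
  set.seed(31)
  true_ic <- 10^stats::runif(200, log10(5), log10(300))
  concs <- c(0, 0.5, 1.6, 5, 16, 50, 160, 500, 1000)
  rel_err <- vapply(seq_along(true_ic), function(i) {
    a <- simulate_competition_assay(competition_params(100, 0, true_ic[i]),
                                    concs, 3, noise_sd = 5, seed = 1000L + i)
    fit <- fit_ic50(a)
    if (!fit$converged) return(NA_real_)
    abs(fit$params$ic50_uM - true_ic[i]) / true_ic[i]
  }, numeric(1))
  expect_true(all(!is.na(rel_err)))
  expect_lt(stats::median(rel_err), 0.10)
})

test_that("displacement occupancy algebra matches its closed forms", {
  # no competitor limit
  expect_equal(displacement_occupancy(2, 5, 4, 0), (4 / 2) / (1 + 4 / 2))
  # symmetric saturation: L = KdL, I = KdI
  expect_equal(displacement_occupancy(3, 7, 3, 7), 1 / 3)
  # monotone: decreasing in competitor dose, increasing in competitor Kd
  occ_I <- vapply(c(0, 1, 5, 20), function(I) {
    displacement_occupancy(1, 1, 1, I)
  }, numeric(1))
  expect_true(all(diff(occ_I) < 0))
  occ_Kd <- vapply(c(0.5, 1, 5, 50), function(kd) {
    displacement_occupancy(1, kd, 1, 1)
  }, numeric(1))
  expect_true(all(diff(occ_Kd) > 0))
})

test_that("affinity tiers separate weak binders per dcTPR protein", {
  fits <- reported_ic50_table()
  names(fits)[names(fits) == "ic50_uM"] <- "ic50_uM"
  tiers <- classify_affinity_tiers(fits, fold_threshold = 10)
  low <- tiers[tiers$tier == "low", ]
  expect_setequal(paste(low$dctpr, low$peptide),
                  c("FKBP51 Tom20", "FKBP51 p23", "AIP Tom20"))
  expect_true(all(tiers$tier[tiers$dctpr == "FKBP51" &
                               !(tiers$peptide %in% c("Tom20", "p23"))] ==
                    "high"))
  # all-equal IC50s: everything high-affinity
  eq <- data.frame(dctpr = "X", peptide = c("a", "b", "c"), ic50_uM = 5)
  expect_true(all(classify_affinity_tiers(eq)$tier == "high"))
  # threshold 1: only the minimum (with ties) is high-affinity
  mix <- data.frame(dctpr = "X", peptide = c("a", "b", "c", "d"),
                    ic50_uM = c(2, 2, 3, 9))
  t1 <- classify_affinity_tiers(mix, fold_threshold = 1)
  expect_equal(t1$tier, c("high", "high", "low", "low"))
  # single fit per protein cannot be classified
  single <- data.frame(dctpr = "Y", peptide = "a", ic50_uM = 4)
  expect_equal(classify_affinity_tiers(single)$tier, "unclassified")
})
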