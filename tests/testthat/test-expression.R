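test_that("RPKM follows its definition and conserves totals", {
  counts <- matrix(c(10, 0, 990, 100, 50, 200), 3, 2,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  counts["g3", "s1"] <- 1e6 - 10   # library size 1e6 for s1
  lens <- c(g1 = 1000, g2 = 500, g3 = 2000)
  rpkm <- computeRpkm(counts, lens)
  expect_equal(rpkm["g1", "s1"], 10 * 1e9 / (1000 * 1e6))
  expect_equal(rpkm["g2", "s1"], 0)

  # doubling all counts of a sample leaves its RPKM unchanged
  doubled <- counts; doubled[, "s2"] <- 2 * counts[, "s2"]
  expect_equal(computeRpkm(doubled, lens)[, "s2"], rpkm[, "s2"])

  # total conservation: sum rpkm * len/1e3 * lib/1e6 returns the counts
  lib <- colSums(counts)
  for (s in colnames(counts)) {
    back <- sum(rpkm[, s] * lens / 1e3 * lib[s] / 1e6)
    expect_equal(back, sum(counts[, s]), tolerance = 1e-6)
  }

  zero <- counts; zero[, "s1"] <- 0
  expect_error(computeRpkm(zero, lens), "zero library")
  expect_error(computeRpkm(counts, lens[1:2]), "exon length missing")
})

test_that("tissue profiles are replicate-averaged log2 values", {
  m <- matrix(c(7, 7, 3, 15, 0, 0), 2, 3, byrow = FALSE,
              dimnames = list(c("gA", "gB"),
                              c("root_r1", "root_r2", "leaf_r1")))
  m["gA", ] <- c(7, 7, 0)        # log2(8) = 3 twice, log2(1) = 0
  m["gB", ] <- c(3, 15, 7)       # log2 4 and 16 -> mean 3
  meta <- S4Vectors::DataFrame(
    condition = c("root", "root", "leaf"), replicate = c(1, 2, 1),
    row.names = colnames(m))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(value = m), colData = meta)
  prof <- tissueProfile(se, c("gA", "gB"))
  expect_equal(prof["gA", "root"], 3)
  expect_equal(prof["gA", "leaf"], 0)
  expect_equal(prof["gB", "root"], 3)
  expect_warning(p2 <- tissueProfile(se, c("gA", "gMissing")), "gMissing")
  expect_true(all(is.na(p2["gMissing", ])))
})

test_that("probe filtering applies the strict retention rule", {
  probes <- data.frame(
    probe_id = c("keep", "mm", "multi", "intron", "ambig", "ambig"),
    gene_id = c("g1", "g1", "g1", "g1", "g2", "g3"),
    mismatches = c(0L, 1L, 0L, 0L, 0L, 0L),
    n_genomic_hits = c(1L, 1L, 2L, 1L, 1L, 1L),
    in_exon = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  kept <- probeFilter(probes)
  expect_equal(kept$probe_id, "keep")
  # order invariance
  shuffled <- probes[c(5, 3, 1, 6, 2, 4), ]
  expect_equal(probeFilter(shuffled), kept)
})

test_that("the SAM d statistic matches its closed forms", {
  expect_equal(samDStatistic(c(4, 5, 6), c(4, 5, 6), s0 = 0.1), 0)
  # pure shift with zero within-group variance: d = c / s0
  expect_equal(samDStatistic(c(5, 5, 5), c(2, 2, 2), s0 = 0.5), 3 / 0.5)
  expect_error(samDStatistic(c(5, 5), c(2, 2), s0 = 0), "zero variance")
  expect_error(samDStatistic(5, c(2, 2), s0 = 1), "2 replicates")

  # 4v4 case against a hand-computed pooled standard error
  x <- c(6.1, 5.8, 6.4, 6.0); y <- c(5.0, 5.3, 4.8, 5.2)
  ss <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  sPool <- sqrt((1 / 4 + 1 / 4) * ss / 6)
  expect_equal(samDStatistic(x, y, s0 = 0.2),
               (mean(x) - mean(y)) / (sPool + 0.2))
})

test_that("permutation q-values agree with the brute-force 3v3 oracle", {
  withr::with_seed(71, {
    mat <- matrix(rnorm(12 * 6, 5, 1), 12, 6)
    mat[1:2, 1:3] <- mat[1:2, 1:3] + 3
    rownames(mat) <- sprintf("g%02d", 1:12)
    isStress <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
    res <- permutationQvalues(mat, isStress, s0 = 0.1,
                              params = deParams(nPermutations = 100))
    oracle <- bruteQvalues(mat, isStress, s0 = 0.1)
    expect_equal(unname(res$qvalue), oracle, tolerance = 1e-12)
    # the gene with the largest |d| attains the smallest q
    expect_equal(unname(res$qvalue[which.max(abs(res$d))]),
                 min(res$qvalue))
  })
})

test_that("calls gate on both fold change and q", {
  p <- deParams()
  expect_equal(deCall(1.5, 0.01, p), "up")
  expect_equal(deCall(0.5, 0.001, p), "none")
  expect_equal(deCall(-2, 0.2, p), "none")
  expect_equal(deCall(-2, 0.01, p), "down")
  pfc <- deParams(fcOnly = TRUE)
  expect_equal(deCall(-2, NA, pfc), "down")
})

test_that("null data are calibrated and power rises with effect size", {
  params <- simParams(seed = 3, nDecoys = 120, nAP2 = 2, nRAV = 2,
                      nDREB = 3, nERF = 3, tandemSizes = integer(0),
                      tandemIdentities = numeric(0), nSegmental = 0,
                      deFraction = 0, timepoints = 1)
  truth <- list(members = data.frame(
    gene_id = sprintf("m%d", 1:10), protein_id = sprintf("m%d.1", 1:10),
    subfamily = "DREB", stringsAsFactors = FALSE),
    decoys = sprintf("d%d", 1:190), tandem = list(), segmental = list())
  fpp <- vapply(1:50, function(i) {
    expr <- genExpression(params, truth, seed = 1000 + i)
    de <- stressDE(expr$stress, deParams(seed = i))
    q <- SummarizedExperiment::assay(de, "qvalue")
    mean(q <= 0.05)
  }, numeric(1))
  expect_lte(median(fpp), 0.075)

  # planted log2 effects 0.5 / 1 / 2 give non-decreasing detection
  rates <- vapply(c(0.5, 1, 2), function(eff) {
    p2 <- simParams(seed = 5, deFraction = 1, effectSize = eff,
                    timepoints = 1, noiseSd = 0.5)
    ex <- genExpression(p2, truth, seed = 777)
    de <- stressDE(ex$stress, deParams(seed = 9))
    q <- SummarizedExperiment::assay(de, "qvalue")
    planted <- ex$truth$deEffects
    hit <- mapply(function(g, st) {
      q[g, sprintf("%s_1h", st)] <= 0.05
    }, planted$gene_id, planted$stress)
    mean(hit)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gte(rates[3], 0.8)
})

test_that("contrasts without replication fall back to fold-change calls", {
  withr::with_seed(73, {
    m <- matrix(2^rnorm(20, 5, 1), 10, 2,
                dimnames = list(sprintf("g%d", 1:10), c("cold_1", "ctl_1")))
    meta <- S4Vectors::DataFrame(
      condition = c("cold", "control"), timepoint_hours = c(1, 1),
      replicate = c(1, 1), row.names = colnames(m))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(value = m), colData = meta)
    expect_warning(de <- stressDE(se), "FALLBACK")
    expect_true(all(is.na(SummarizedExperiment::assay(de, "qvalue"))))
    fc <- SummarizedExperiment::assay(de, "log2fc")
    calls <- SummarizedExperiment::assay(de, "call")
    expect_equal(unname(calls[, 1] != "none"), unname(abs(fc[, 1]) > 1))
  })
})

test_that("stress DE on synthetic data meets recall and FDR targets", {
  study <- syntheticStudy()
  expr <- genExpression(study$params, study$gen$truth)
  de <- stressDE(expr$stress, deParams(seed = 17))
  calls <- SummarizedExperiment::assay(de, "call")
  eff <- expr$truth$effectMatrix
  colnames(eff) <- colnames(calls)
  planted <- abs(eff) >= 2 &
    matrix(rownames(eff) %in% expr$truth$deEffects$gene_id,
           nrow(eff), ncol(eff))
  called <- calls != "none"
  recall <- sum(called & planted) / sum(planted)
  fdr <- sum(called & eff == 0) / max(1, sum(called))
  expect_gte(recall, 0.8)
  expect_lte(fdr, 0.1)
})
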