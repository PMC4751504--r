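test_that("profile construction follows the pseudocounted log-odds model", {
  # 5 identical ungapped sequences of length 12
  seqs <- Biostrings::AAStringSet(rep("ACDEFGHIKLMN", 5))
  prof <- buildProfile(seqs, "T")
  expect_equal(length(prof), 12L)
  expect_equal(profileConsensus(prof), "ACDEFGHIKLMN")
  expect_equal(unname(prof@scores[, "X"]), rep(0, 12))
  expect_equal(sum(prof@background), 1, tolerance = 1e-12)

  # one all-gap column is dropped
  gappy <- Biostrings::AAStringSet(rep("ACDEF-GHIKLMN", 5))
  expect_equal(length(buildProfile(gappy, "T")), 12L)

  # recompute the log-odds of one column by hand: column 1 has {A:3, V:2}
  # atop an otherwise diverse alignment
  m <- c("ACDEFGHIKLMW", "ACDEFGHIKLMW", "ANPQRSTVWYCM",
         "VNPQRSTVWYCM", "VCDEFGHIKLMW")
  prof2 <- buildProfile(Biostrings::AAStringSet(m), "T")
  res <- unlist(strsplit(m, ""))
  nRes <- length(res)
  bg <- function(a) (sum(res == a) + 0.1) / (nRes + 2.1)
  expectA <- log2(((3 + 0.1) / (5 + 2.1)) / bg("A"))
  expectV <- log2(((2 + 0.1) / (5 + 2.1)) / bg("V"))
  expectW <- log2(((0 + 0.1) / (5 + 2.1)) / bg("W"))
  expect_equal(unname(prof2@scores[1, "A"]), expectA, tolerance = 1e-12)
  expect_equal(unname(prof2@scores[1, "V"]), expectV, tolerance = 1e-12)
  expect_equal(unname(prof2@scores[1, "W"]), expectW, tolerance = 1e-12)
  expect_true(prof2@scores[1, "A"] > prof2@scores[1, "V"])
  expect_true(prof2@scores[1, "V"] > prof2@scores[1, "W"])
  expect_equal(substr(profileConsensus(prof2), 1, 1), "A")

  expect_error(buildProfile(Biostrings::AAStringSet(
    c(rep("ACDEFGHIKLMN", 4), "ACDEF")), "T"), "ragged")
  expect_error(buildProfile(Biostrings::AAStringSet(
    rep("ACDEFGHIKLMN", 4)), "T"), "at least 5")
})

test_that("scanning finds planted consensus and separates two copies", {
  prof <- smallProfile()
  cons <- profileConsensus(prof)
  L <- length(prof)
  withr::with_seed(42, {
    seq1 <- paste0(randStr(7), cons, randStr(40))
    hits <- scanSequence(prof, seq1)
    expect_equal(hits$start[1], 7L)
    # the planted consensus attains the maximum full-window score
    consScore <- sum(prof@scores[cbind(seq_len(L),
                                       match(strsplit(cons, "")[[1]],
                                             colnames(prof@scores)))])
    expect_equal(hits$score[1], consScore, tolerance = 1e-9)

    # two copies separated by 2L background residues -> exactly 2 hits
    seq2 <- paste0(randStr(11), cons, randStr(2 * L), cons, randStr(9))
    hits2 <- scanSequence(prof, seq2)
    expect_equal(nrow(hits2), 2L)
    expect_setequal(hits2$start, c(11L, 11L + L + 2L * L))
    # brute-force check: both accepted windows are the two top-scoring
    # non-overlapping full windows
    sint <- match(strsplit(seq2, "")[[1]], colnames(prof@scores))
    n <- length(sint)
    w <- vapply(seq_len(n - L + 1), function(i)
      sum(prof@scores[cbind(seq_len(L), sint[i:(i + L - 1)])]), numeric(1))
    expect_setequal(hits2$start, order(w, decreasing = TRUE)[1:2] - 1L)
  })

  # sequence shorter than L/2: only truncated hits or nothing
  short <- scanSequence(prof, substr(cons, 1, floor(L / 2) - 1))
  expect_true(nrow(short) == 0 || all(short$truncated))
  expect_equal(nrow(scanSequence(prof, "")), 0L)
})

test_that("Gumbel calibration gives the stated E-value semantics", {
  prof <- smallProfile(seed = 6, calibrated = FALSE)
  expect_error(calibrateNull(prof, nShuffles = 100), ">= 200")
  cal <- calibrateNull(prof, nShuffles = 1000, length = 60, seed = 3)
  # E at s = mu with D = 1 is 1 - exp(-1)
  expect_equal(evalueFromScore(cal, cal@nullMu, D = 1), 1 - exp(-1),
               tolerance = 1e-12)
  # strictly decreasing in s
  s <- seq(cal@nullMu - 10, cal@nullMu + 10, length.out = 50)
  expect_true(all(diff(evalueFromScore(cal, s)) < 0))
  # empirical tail mass above the fitted 95th percentile
  q95 <- cal@nullMu - cal@nullBeta * log(-log(0.95))
  frac <- mean(cal@nullScores >= q95)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  # determinism: same seed, bit-identical null
  cal2 <- calibrateNull(prof, nShuffles = 1000, length = 60, seed = 3)
  expect_identical(cal@nullScores, cal2@nullScores)
})

test_that("planted domains are recovered within 2 residues of the truth", {
  prof <- smallProfile(seed = 7, L = 30, calibrated = TRUE)
  cons <- profileConsensus(prof)
  ok <- withr::with_seed(99, {
    vapply(1:500, function(i) {
      off <- sample(0:80, 1)
      dom <- mutateStr(cons, 0.05)
      seq <- paste0(randStr(off), dom, randStr(sample(20:80, 1)))
      h <- scanSequence(prof, seq)
      nrow(h) >= 1 && abs(h$start[1] - off) <= 2 &&
        abs(h$end[1] - (off + nchar(cons))) <= 2
    }, logical(1))
  })
  expect_gte(mean(ok), 0.99)
})

test_that("background-sampled decoys rarely produce significant hits", {
  # calibrate at the decoy length, as the pipeline calibrates at the mean
  # scanned-protein length
  prof <- calibrateNull(smallProfile(seed = 8, L = 30, calibrated = FALSE),
                        nShuffles = 500, length = 150, seed = 9)
  bgDecoy <- function(n) {
    paste(sample(colnames(prof@scores), n, replace = TRUE,
                 prob = prof@background), collapse = "")
  }
  falseHits <- withr::with_seed(123, {
    sum(vapply(1:500, function(i) {
      h <- scanSequence(prof, bgDecoy(150), D = 500)
      sum(h$evalue < 1.0)
    }, numeric(1)))
  })
  expect_gte(falseHits, 0)
  expect_lte(falseHits, 5)
})

test_that("profiles and hits are deterministic and serialize to TSV", {
  prof <- smallProfile(seed = 9)
  h1 <- scanSequence(prof, paste0(profileConsensus(prof), "ACDEF"))
  h2 <- scanSequence(prof, paste0(profileConsensus(prof), "ACDEF"))
  expect_identical(h1, h2)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeProfileTsv(prof, p)
  back <- readProfileTsv(p)
  expect_equal(back@scores, prof@scores, tolerance = 1e-15)
  expect_equal(back@nullMu, prof@nullMu, tolerance = 1e-15)
  expect_equal(profileConsensus(back), profileConsensus(prof))
})
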