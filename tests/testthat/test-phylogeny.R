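test_that("profile anchoring projects subsequences onto match columns", {
  prof <- smallProfile(seed = 25, L = 20, calibrated = FALSE)
  cons <- profileConsensus(prof)
  del5 <- paste0(substr(cons, 1, 4), substr(cons, 6, 20))
  ins <- paste0(substr(cons, 1, 10), "AAA", substr(cons, 11, 20))
  msa <- anchorMSA(prof, c(exact = cons, del = del5, ins = ins))
  m <- msaMatrix(msa)
  expect_equal(paste(m["exact", ], collapse = ""), cons)
  expect_equal(unname(m["del", 5]), "-")
  expect_equal(paste(m["del", -5], collapse = ""),
               paste(strsplit(cons, "")[[1]][-5], collapse = ""))
  # insertions are projected out: the row equals the consensus
  expect_equal(paste(m["ins", ], collapse = ""), cons)

  expect_warning(
    anchorMSA(prof, c(exact = cons, junk = substr(cons, 1, 3))),
    "fewer than")
})

test_that("p-distance uses pairwise deletion", {
  msa <- new("AnchoredMSA", ids = c("a", "b", "c"),
             rows = c("ACDE", "ACDK", "A-DE"), profileName = "T")
  dm <- pDistance(msa)
  expect_equal(dm$d["a", "a"], 0)
  expect_equal(dm$d["a", "b"], 0.25)      # 1 mismatch / 4 sites
  expect_equal(dm$d["b", "c"], 1 / 3)     # pairwise deletion leaves 3
  expect_equal(dm$d["a", "c"], 0)
  expect_true(isSymmetric(dm$d))

  bad <- new("AnchoredMSA", ids = c("a", "b", "c"),
             rows = c("AC--", "--DE", "ACDE"), profileName = "T")
  expect_error(pDistance(bad), "no shared non-gap columns")

  # Poisson correction is -ln(1 - p)
  dp <- pDistance(msa, model = "poisson")
  expect_equal(dp$d["a", "b"], -log(1 - 0.25))
})

test_that("neighbor joining matches the closed form for three taxa", {
  d <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(distanceMatrix(d))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (3 + 8 - 9) / 2)
  expect_equal(unname(bl["B"]), (3 + 9 - 8) / 2)
  expect_equal(unname(bl["C"]), (8 + 9 - 3) / 2)

  asym <- d; asym[1, 2] <- 5
  expect_error(njTree(distanceMatrix(asym)), "symmetric")
})

test_that("neighbor joining is consistent on additive distances", {
  withr::with_seed(41, {
    for (i in 1:20) {
      case <- randomAdditiveCase(sample(8:16, 1))
      tr <- njTree(distanceMatrix(case$d))
      expect_equal(rfDist(tr, case$tree), 0)
    }
  })
})

test_that("neighbor joining equals the brute-force transcription", {
  withr::with_seed(43, {
    for (i in 1:50) {
      n <- sample(4:5, 1)
      m <- matrix(runif(n * n, 0.1, 2), n, n)
      d <- (m + t(m)) / 2; diag(d) <- 0
      dimnames(d) <- list(letters[1:n], letters[1:n])
      mine <- njTree(distanceMatrix(d))
      oracle <- njOracle(d)
      expect_equal(rfDist(mine, oracle), 0)
      expect_equal(sort(mine$edge.length), sort(oracle$edge.length),
                   tolerance = 1e-9)
      # and the ape implementation agrees on topology
      expect_equal(rfDist(mine, ape::nj(d)), 0)
    }
  })
})

test_that("negative branch lengths are clamped with raw values kept", {
  # distances violating additivity can push NJ branch lengths negative
  found <- FALSE
  withr::with_seed(47, {
    for (i in 1:50) {
      n <- 5
      m <- matrix(runif(n * n, 0.05, 1), n, n)
      d <- (m + t(m)) / 2; diag(d) <- 0
      dimnames(d) <- list(letters[1:n], letters[1:n])
      tr <- njTree(distanceMatrix(d))
      raw <- attr(tr, "rawTree")
      expect_true(all(tr$edge.length >= 0))
      expect_equal(tr$edge.length[raw$edge.length >= 0],
                   raw$edge.length[raw$edge.length >= 0], tolerance = 1e-9)
      if (any(raw$edge.length < 0)) found <- TRUE
    }
  })
  expect_true(found)
})

test_that("bootstrap supports behave as counts over replicates", {
  # two tight 5-clone groups: the single split is found in every replicate
  withr::with_seed(53, {
    gA <- randStr(40); gB <- mutateStr(gA, 0.5)
    rows <- c(vapply(1:5, function(i) mutateStr(gA, 0.02), character(1)),
              vapply(1:5, function(i) mutateStr(gB, 0.02), character(1)))
    msa <- new("AnchoredMSA", ids = sprintf("t%02d", 1:10), rows = rows,
               profileName = "T")
    tr <- bootstrapSupport(msa, B = 50, seed = 1)
    supports <- tr$node.label[-1]
    expect_true(all(supports <= 50))
    expect_true(max(supports) == 50)  # the A/B split edge

    tr1 <- bootstrapSupport(msa, B = 1, seed = 2)
    expect_true(all(tr1$node.label[-1] %in% c(0L, 1L)))

    # invariance to leaf order permutation of the input MSA
    perm <- sample(10)
    msaP <- new("AnchoredMSA", ids = msa@ids[perm], rows = rows[perm],
                profileName = "T")
    trP <- bootstrapSupport(msaP, B = 50, seed = 1)
    key <- function(t) {
      s <- t$node.label[-1]
      pp <- ape::prop.part(t)
      labs <- attr(pp, "labels")
      sort(vapply(seq_along(pp)[-1], function(k)
        paste0(paste(sort(labs[pp[[k]]]), collapse = ","), "=",
               s[k - 1]), character(1)))
    }
    expect_identical(key(tr), key(trP))
  })
})

test_that("anchor labelling assigns clades and never forces mixtures", {
  # tree with a pure DREB clade, a pure ERF clade, and a query sister to
  # a mixed clade
  tr <- ape::read.tree(text = paste0(
    "(((d1:1,d2:1):1,q1:1):1,((e1:1,e2:1):1,q2:1):1,",
    "(q3:1,(d3:1,e3:1):1):1);"))
  anchors <- c(d1 = "DREB", d2 = "DREB", d3 = "DREB",
               e1 = "ERF", e2 = "ERF", e3 = "ERF")
  lab <- labelGroups(tr, anchors)
  expect_equal(unname(lab["q1"]), "DREB")
  expect_equal(unname(lab["q2"]), "ERF")
  expect_equal(unname(lab["q3"]), "unclassified")
  expect_equal(unname(lab["d1"]), "DREB")  # anchor keeps its own label

  noAnchor <- ape::read.tree(text = "(x:1,y:1,z:1);")
  expect_error(labelGroups(noAnchor, anchors), "no anchor")
})

test_that("planted groups are recovered from per-group consensus draws", {
  prof <- smallProfile(seed = 57, L = 30, calibrated = FALSE)
  acc <- withr::with_seed(59, {
    consA <- randStr(30); consB <- mutateStr(consA, 0.4)
    nQ <- 20
    rows <- c(
      vapply(1:4, function(i) mutateStr(consA, 0.05), character(1)),
      vapply(1:4, function(i) mutateStr(consB, 0.05), character(1)),
      vapply(1:nQ, function(i)
        mutateStr(if (i <= nQ / 2) consA else consB, 0.05), character(1)))
    ids <- c(sprintf("anchorA%d", 1:4), sprintf("anchorB%d", 1:4),
             sprintf("q%02d", 1:nQ))
    msa <- new("AnchoredMSA", ids = ids, rows = rows, profileName = "T")
    tr <- njTree(pDistance(msa))
    anchors <- setNames(rep(c("A", "B"), each = 4), ids[1:8])
    lab <- labelGroups(tr, anchors)
    truthLab <- rep(c("A", "B"), each = nQ / 2)
    mean(lab[sprintf("q%02d", 1:nQ)] == truthLab)
  })
  expect_gte(acc, 0.95)
})

test_that("synthetic members get their planted DREB/ERF groups", {
  study <- syntheticStudy()
  res <- study$idres
  gen <- study$gen
  dom <- bestDomainSubsequences(res$members, res$hits, gen$proteome)
  msa <- anchorMSA(study$profiles[[1]],
                   c(dom, setNames(gen$anchors$seq, gen$anchors$id)))
  tr <- njTree(pDistance(msa))
  lab <- labelGroups(tr, setNames(gen$anchors$label, gen$anchors$id))
  truth <- gen$truth$members
  planted <- truth$subfamily[match(sub("[.]1$", "", names(dom)),
                                   truth$gene_id)]
  sel <- planted %in% c("DREB", "ERF")
  expect_equal(mean(lab[names(dom)][sel] == planted[sel]), 1.0)
})
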