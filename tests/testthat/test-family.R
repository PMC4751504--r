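test_that("isoform collapse keeps the longest protein per gene", {
  annot <- miniAnnotation(geneLens = c(900L, 900L, 900L),
                          isoLens = c(750L, NA, 900L))
  proteome <- Biostrings::AAStringSet(c(
    g1.1 = randStr(300), g1.2 = randStr(250),
    g2.1 = randStr(280),
    g3.1 = randStr(300), g3.2 = randStr(300)))
  cand <- data.frame(protein_id = names(proteome),
                     evidence = "profile", stringsAsFactors = FALSE)
  res <- collapseIsoforms(cand, annot, proteome)
  expect_setequal(res$members$protein_id, c("g1.1", "g2.1", "g3.1"))
  expect_equal(res$exclusions$reason, rep("splice_variant", 2))
  expect_setequal(res$exclusions$protein_id, c("g1.2", "g3.2"))
  # tie on length: lexicographically smallest protein id wins (g3.1)
  expect_true("g3.1" %in% res$members$protein_id)

  bad <- rbind(cand, data.frame(protein_id = "gX.1", evidence = "profile"))
  expect_error(collapseIsoforms(bad, annot, proteome), "gX.1")
})

test_that("exclusion rules separate short, divergent and absent domains", {
  prof <- smallProfile(seed = 21, L = 30)
  members <- data.frame(protein_id = c("pShort", "pDiv", "pGood", "pNone"),
                        gene_id = paste0("g", 1:4), evidence = "profile",
                        stringsAsFactors = FALSE)
  hits <- rbind(
    data.frame(protein_id = "pShort", domain = "TEST", start = 0, end = 9,
               score = 30, evalue = 0.01, truncated = TRUE),
    data.frame(protein_id = "pDiv", domain = "TEST", start = 0, end = 30,
               score = 5, evalue = 5, truncated = FALSE),
    data.frame(protein_id = "pGood", domain = "TEST", start = 3, end = 33,
               score = 80, evalue = 1e-9, truncated = FALSE))
  res <- exclusionFilter(members, hits, list(prof))
  expect_equal(res$members$protein_id, "pGood")
  ex <- res$exclusions
  expect_equal(ex$reason[ex$protein_id == "pShort"], "short_domain")
  expect_equal(ex$reason[ex$protein_id == "pDiv"], "divergent_domain")
  expect_equal(ex$reason[ex$protein_id == "pNone"], "no_domain")
})

test_that("architecture classification maps hit patterns to subfamilies", {
  h <- function(doms, trunc = rep(FALSE, length(doms))) {
    data.frame(domain = doms, truncated = trunc)
  }
  expect_equal(classifyArchitecture(h(c("AP2", "AP2"))), "AP2")
  expect_equal(classifyArchitecture(h(c("AP2", "B3"))), "RAV")
  expect_equal(classifyArchitecture(h("AP2")), "DREB_ERF_unresolved")
  expect_warning(out <- classifyArchitecture(h(c("AP2", "AP2", "AP2"))),
                 "3 complete")
  expect_equal(out, "AP2")
  # a truncated second AP2 does not count as complete
  expect_equal(classifyArchitecture(h(c("AP2", "AP2"), c(FALSE, TRUE))),
               "DREB_ERF_unresolved")
  expect_error(classifyArchitecture(h("B3")), "zero")
})

test_that("naming follows chromosomal order with deterministic ties", {
  members <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    subfamily = c("DREB", "DREB", "DREB", "RAV", "DREB"),
    chrom = c("Bd2", "Bd1", "Bd10", "Bd2", "Bd1"),
    start = c(50L, 100L, 10L, 5L, 100L),
    end = c(60L, 200L, 20L, 6L, 150L),
    stringsAsFactors = FALSE)
  named <- assignNames(members, "Bd")
  dreb <- named[named$subfamily == "DREB", ]
  # Bd1 < Bd2 < Bd10 (natural order); same chrom+start: end breaks the tie
  expect_equal(dreb$gene_id, c("g5", "g2", "g1", "g3"))
  expect_equal(dreb$assigned_name,
               c("BdDREB-1", "BdDREB-2", "BdDREB-3", "BdDREB-4"))
  expect_equal(named$assigned_name[named$subfamily == "RAV"], "BdRAV-1")

  # invariance to input row order
  shuffled <- members[c(4, 2, 5, 1, 3), ]
  expect_equal(assignNames(shuffled, "Bd"), named)

  members$subfamily[1] <- "DREB_ERF_unresolved"
  expect_error(assignNames(members, "Bd"), "unresolved")
})

test_that("candidate routes record profile and similarity evidence", {
  prof <- smallProfile(seed = 23, L = 30)
  cons <- profileConsensus(prof)
  withr::with_seed(31, {
    query <- paste0(randStr(20), cons, randStr(30))        # family query
    hasDomain <- paste0(randStr(15), mutateStr(cons, 0.05), randStr(25))
    # similar to the query over its full length but domain destroyed
    degenerate <- mutateStr(query, 0.10)
    degenerate <- paste0(substr(degenerate, 1, 20),
                         randStr(nchar(cons)),
                         substr(degenerate, 21 + nchar(cons), nchar(degenerate)))
    decoy <- randStr(80)
    proteome <- Biostrings::AAStringSet(c(pDom = hasDomain,
                                          pSim = degenerate,
                                          pDecoy = decoy))
    res <- collectCandidates(proteome, list(prof),
                             Biostrings::AAStringSet(c(q1 = query)))
    ev <- setNames(res$candidates$evidence, res$candidates$protein_id)
    expect_equal(unname(ev["pDom"]), "profile")
    expect_equal(unname(ev["pSim"]), "similarity")
    expect_false("pDecoy" %in% names(ev))
  })

  uncal <- buildProfile(Biostrings::AAStringSet(
    replicate(5, randStr(30))), "RAW")
  expect_error(collectCandidates(
    Biostrings::AAStringSet(c(p = randStr(50))), list(uncal),
    Biostrings::AAStringSet(c(q = randStr(50)))), "calibrated")
})

test_that("identification on the synthetic genome recovers planted truth", {
  study <- syntheticStudy()
  truth <- study$gen$truth
  res <- study$idres

  found <- res$members$gene_id
  tp <- length(intersect(found, truth$members$gene_id))
  fp <- length(setdiff(found, truth$members$gene_id))
  fn <- length(setdiff(truth$members$gene_id, found))
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_equal(f1, 1.0)

  # architecture agrees with the planted one for every member
  merged <- merge(res$members[, c("gene_id", "subfamily")],
                  truth$members[, c("gene_id", "subfamily")], by = "gene_id")
  planted <- ifelse(merged$subfamily.y %in% c("DREB", "ERF"),
                    "DREB_ERF_unresolved", merged$subfamily.y)
  expect_equal(mean(merged$subfamily.x == planted), 1.0)

  # candidates partition into retained members and exclusions
  expect_equal(sort(c(res$members$protein_id, res$exclusions$protein_id)),
               sort(unique(c(res$members$protein_id,
                             res$exclusions$protein_id))))
  # every planted isoform of a member gene was excluded as splice variant
  iso <- truth$isoforms$protein_id
  expect_true(all(iso %in%
    res$exclusions$protein_id[res$exclusions$reason == "splice_variant"]))
})
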