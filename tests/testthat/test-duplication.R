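test_that("tandem adjacency allows at most one intervening gene", {
  withr::with_seed(61, {
    founder <- randStr(300)
    near <- mutateStr(founder, 0.1)  # ~0.9 identity, passes stringent
    for (gap in 0:2) {
      sc <- dupScaffold(c(mA = founder, mB = near), gaps = gap)
      ev <- tandemClusters(sc$members, sc$proteome, sc$geneOrder,
                           dupParams("stringent"))
      if (gap <= 1) {
        expect_length(ev, 1)
        expect_setequal(ev[[1]]$gene_ids, c("mA", "mB"))
        expect_equal(ev[[1]]$pairs$intervening, gap)
      } else {
        expect_length(ev, 0)
      }
    }
  })
})

test_that("tandem thresholds gate on the configured metric", {
  withr::with_seed(63, {
    founder <- randStr(300)
    sc <- dupScaffold(c(mA = founder, mB = mutateStr(founder, 0.45)),
                      gaps = 0)
    # ~0.55 identity: fails stringent similarity-metric thresholds,
    # passes relaxed
    expect_length(tandemClusters(sc$members, sc$proteome, sc$geneOrder,
                                 dupParams("stringent")), 0)
    expect_length(tandemClusters(sc$members, sc$proteome, sc$geneOrder,
                                 dupParams("relaxed")), 1)

    expect_error(tandemClusters(sc$members, sc$proteome,
                                list(Chr1 = "other"), dupParams()),
                 "absent from the gene order")
  })
})

test_that("relaxed mode detects a superset of stringent events", {
  withr::with_seed(65, {
    founder <- randStr(250)
    seqs <- c(m1 = founder, m2 = mutateStr(founder, 0.08),
              m3 = mutateStr(founder, 0.35), m4 = randStr(250))
    sc <- dupScaffold(seqs, gaps = c(0, 1, 1))
    str <- tandemClusters(sc$members, sc$proteome, sc$geneOrder,
                          dupParams("stringent"))
    rel <- tandemClusters(sc$members, sc$proteome, sc$geneOrder,
                          dupParams("relaxed"))
    strGenes <- unlist(lapply(str, `[[`, "gene_ids"))
    relGenes <- unlist(lapply(rel, `[[`, "gene_ids"))
    expect_true(all(strGenes %in% relGenes))
    expect_gte(length(relGenes), length(strGenes))
  })
})

test_that("planted tandem clusters are recovered exactly", {
  study <- syntheticStudy()
  gen <- study$gen
  truth <- gen$truth
  gt <- geneTable(gen$annot)
  members <- truth$members
  members$chrom <- gt$chrom[match(members$gene_id, gt$gene_id)]
  members$start <- gt$start[match(members$gene_id, gt$gene_id)]
  members$end <- gt$end[match(members$gene_id, gt$gene_id)]
  ev <- tandemClusters(members, gen$proteome,
                       geneOrderFromAnnotation(gen$annot),
                       dupParams("stringent"))
  got <- lapply(ev, function(e) sort(e$gene_ids))
  want <- lapply(truth$tandem, function(e) sort(e$gene_ids))
  expect_equal(length(got), length(want))
  for (w in want) {
    expect_true(any(vapply(got, identical, logical(1), w)))
  }
})

test_that("segmental pairs require a shared block and exclusivity", {
  withr::with_seed(67, {
    founder <- randStr(300)
    members <- data.frame(
      gene_id = c("sA", "sB", "sC"),
      protein_id = c("sA.1", "sB.1", "sC.1"),
      chrom = c("Chr1", "Chr3", "Chr2"),
      start = c(100L, 5000L, 900L), end = c(1000L, 5900L, 1800L),
      stringsAsFactors = FALSE)
    proteome <- Biostrings::AAStringSet(c(
      sA.1 = founder, sB.1 = mutateStr(founder, 0.12), sC.1 = randStr(300)))
    blocks <- data.frame(
      block_id = "blk1", species_a = "synth", chrom_a = "Chr1",
      start_a = 0, end_a = 2000, gene_a = "sA",
      species_b = "synth", chrom_b = "Chr3", start_b = 4000, end_b = 7000,
      gene_b = "sB", stringsAsFactors = FALSE)
    ev <- segmentalPairs(members, proteome, blocks, dupParams("stringent"))
    expect_length(ev, 1)
    expect_setequal(ev[[1]]$gene_ids, c("sA", "sB"))
    expect_equal(ev[[1]]$block_id, "blk1")

    # similarity below threshold: no event
    proteome2 <- proteome
    proteome2[["sB.1"]] <- Biostrings::AAString(randStr(300))
    expect_length(segmentalPairs(members, proteome2, blocks,
                                 dupParams("stringent")), 0)

    # already tandem-clustered pairs are not re-reported
    tandemEv <- list(list(gene_ids = c("sA", "sB")))
    expect_length(segmentalPairs(members, proteome, blocks,
                                 dupParams("stringent"), tandemEv), 0)
  })
})

test_that("planted segmental pairs are found via their blocks", {
  study <- syntheticStudy()
  gen <- study$gen
  gt <- geneTable(gen$annot)
  members <- gen$truth$members
  members$chrom <- gt$chrom[match(members$gene_id, gt$gene_id)]
  members$start <- gt$start[match(members$gene_id, gt$gene_id)]
  members$end <- gt$end[match(members$gene_id, gt$gene_id)]
  ev <- segmentalPairs(members, gen$proteome, gen$blocks,
                       dupParams("stringent"))
  got <- lapply(ev, function(e) sort(e$gene_ids))
  for (sv in gen$truth$segmental) {
    expect_true(any(vapply(got, identical, logical(1),
                           sort(c(sv$gene_a, sv$gene_b)))))
  }
})

test_that("ortholog mapping yields one row per anchoring block", {
  members <- data.frame(gene_id = c("m1", "m2", "m3"),
                        stringsAsFactors = FALSE)
  mkRow <- function(bid, ga, sp, gb) {
    data.frame(block_id = bid, species_a = "synth", chrom_a = "Chr1",
               start_a = 0, end_a = 10, gene_a = ga, species_b = sp,
               chrom_b = "c", start_b = 0, end_b = 10, gene_b = gb,
               stringsAsFactors = FALSE)
  }
  blocks <- rbind(
    mkRow("b1", "m1", "rice", "r1"),
    mkRow("b2", "m2", "rice", "r2"),
    mkRow("b3", "m2", "maize", "z2"),
    mkRow("b4", "m2", "sorghum", "s2"),
    # duplicated pair both mapped to the same sorghum gene
    mkRow("b5", "m1", "sorghum", "sShared"),
    mkRow("b6", "m3", "sorghum", "sShared"))
  orth <- mapOrthologs(members, blocks, focalSpecies = "synth")
  expect_equal(sum(orth$table$member_gene == "m1" &
                     orth$table$species == "rice"), 1)
  expect_equal(sum(orth$table$member_gene == "m2"), 3)
  shared <- orth$table[orth$table$ortholog == "sShared", ]
  expect_setequal(shared$member_gene, c("m1", "m3"))
  expect_equal(
    orth$summary$n_members_with_ortholog[orth$summary$species == "sorghum"],
    3L)
})
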