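# Shared fixtures, built once per test run and memoised.

.fixtureEnv <- new.env(parent = emptyenv())

# default synthetic study: genome + calibrated profiles + identification
syntheticStudy <- function() {
  if (!is.null(.fixtureEnv$study)) return(.fixtureEnv$study)
  params <- simParams(seed = 1)
  gen <- genProteomeGff(params)
  meanLen <- as.integer(round(mean(Biostrings::width(gen$proteome))))
  profiles <- list(
    calibrateNull(buildProfile(gen$seeds$AP2, "AP2"), nShuffles = 500,
                  length = meanLen, seed = 11),
    calibrateNull(buildProfile(gen$seeds$B3, "B3"), nShuffles = 500,
                  length = meanLen, seed = 12))
  idres <- identifyFamily(gen$proteome, profiles,
                          setNames(gen$anchors$seq, gen$anchors$id),
                          gen$annot)
  .fixtureEnv$study <- list(params = params, gen = gen, profiles = profiles,
                            idres = idres)
  .fixtureEnv$study
}

# a small calibrated profile over a fixed random consensus
smallProfile <- function(seed = 5, L = 20, nSeqs = 8, mut = 0.1,
                         calibrated = TRUE) {
  key <- paste0("prof", seed, "_", L, "_", nSeqs, "_", mut, "_", calibrated)
  if (!is.null(.fixtureEnv[[key]])) return(.fixtureEnv[[key]])
  prof <- withr::with_seed(seed, {
    cons <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         L, replace = TRUE), collapse = "")
    seqs <- vapply(seq_len(nSeqs), function(i) mutateStr(cons, mut),
                   character(1))
    buildProfile(Biostrings::AAStringSet(seqs), "TEST")
  })
  if (calibrated) prof <- calibrateNull(prof, 300, 2L * L, seed = seed + 1)
  .fixtureEnv[[key]] <- prof
  prof
}

AA20chr <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randStr <- function(n) paste(sample(AA20chr, n, replace = TRUE),
                             collapse = "")

mutateStr <- function(x, rate) {
  v <- strsplit(x, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(AA20chr, v[i]), 1)
  paste(v, collapse = "")
}

# one-chromosome scaffold: family members interleaved with filler genes
dupScaffold <- function(memberSeqs, gaps) {
  # gaps[i]: number of filler genes between member i and member i+1
  order <- character(0)
  members <- names(memberSeqs)
  for (i in seq_along(members)) {
    order <- c(order, members[i])
    if (i <= length(gaps) && gaps[i] > 0) {
      order <- c(order, sprintf("fill_%d_%d", i, seq_len(gaps[i])))
    }
  }
  geneOrder <- list(Chr1 = order)
  membersDf <- data.frame(gene_id = members,
                          protein_id = paste0(members, ".1"),
                          chrom = "Chr1", stringsAsFactors = FALSE)
  proteome <- Biostrings::AAStringSet(setNames(unname(memberSeqs),
                                               paste0(members, ".1")))
  list(members = membersDf, proteome = proteome, geneOrder = geneOrder)
}

# tiny GFF3 text writer for io tests
writeTinyGff <- function(lines, path = withr::local_tempfile(
                           fileext = ".gff3",
                           .local_envir = parent.frame())) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# minimal annotation: one gene per entry, gene ids g1..gn on one chromosome
miniAnnotation <- function(geneLens, chrom = "Chr1", isoLens = NULL) {
  start <- 1L
  lines <- character(0)
  for (i in seq_along(geneLens)) {
    g <- sprintf("g%d", i)
    end <- start + geneLens[i] - 1L
    lines <- c(lines,
      sprintf("%s\tx\tgene\t%d\t%d\t.\t+\t.\tID=%s", chrom, start, end, g),
      sprintf("%s\tx\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.1;Parent=%s",
              chrom, start, end, g, g),
      sprintf("%s\tx\texon\t%d\t%d\t.\t+\t.\tID=%s.1.e1;Parent=%s.1",
              chrom, start, end, g, g))
    if (!is.null(isoLens) && !is.na(isoLens[i])) {
      iend <- start + isoLens[i] - 1L
      lines <- c(lines,
        sprintf("%s\tx\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.2;Parent=%s",
                chrom, start, iend, g, g),
        sprintf("%s\tx\texon\t%d\t%d\t.\t+\t.\tID=%s.2.e1;Parent=%s.2",
                chrom, start, iend, g, g))
    }
    start <- end + 1000L
  }
  readGenomeAnnotation(writeTinyGff(lines, tempfile(fileext = ".gff3")))
}
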