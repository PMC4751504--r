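#' Parameters for the synthetic study generator
#'
#' Defines the study conditions the generator emulates: an annotated
#' five-chromosome genome carrying planted AP2/EREBP-like family members
#' of all three architectures among background decoy genes, tandem
#' clusters with tuned protein identity, segmental pairs with synteny
#' blocks, splice isoforms, and a 4-stress x 5-timepoint expression design
#' with replicated controls, planted fold-change effects and planted
#' duplicate-pair correlations.
#'
#' @param seed Master RNG seed.
#' @param nChromosomes Number of chromosomes (default 5).
#' @param nDecoys Background genes without planted domains (default 200).
#' @param nAP2,nRAV,nDREB,nERF Planted members per architecture
#'   (defaults 12/8/20/20, ~60 members in total).
#' @param domainMutationRate Per-site substitution rate applied to each
#'   planted domain copy (default 0.05).
#' @param variantDivergence Divergence of the DREB- and ERF-specific
#'   domain variants from the base consensus (default 0.25) -- what makes
#'   the two single-domain subfamilies phylogenetically separable.
#' @param seedN,seedMutationRate Seed-alignment depth and per-site
#'   divergence (defaults 12 and 0.15).
#' @param ap2Length,b3Length Domain lengths (defaults 60 and 50).
#' @param proteinLengthRange Member/decoy protein lengths (default
#'   280-450).
#' @param isoformFraction Fraction of member genes emitting a truncated
#'   second isoform (default 0.2).
#' @param tandemSizes,tandemIdentities Tandem cluster sizes and target
#'   global-alignment identities (defaults: one 3-gene cluster at 0.85,
#'   one 2-gene cluster at 0.80).
#' @param nSegmental Segmental pairs (default 2) planted at
#'   `segmentalIdentity` (default 0.80).
#' @param nAnchorsPerGroup Labelled DREB/ERF anchor sequences (default 5
#'   each).
#' @param stresses,timepoints Stress x timepoint grid (defaults: cold,
#'   heat, drought, salt x 1, 2, 5, 10, 24 h).
#' @param replicates Replicates per stress x timepoint and per control
#'   timepoint (default 4).
#' @param noiseSd Replicate noise standard deviation on the log2 scale
#'   (default 0.5, a typical array-replicate spread).
#' @param effectSize Planted DE log2 effect magnitude (default 2).
#' @param deFraction Fraction of non-duplicated members given a planted
#'   DE effect (default 0.4).
#' @param effectProfileSd Standard deviation of latent effect profiles
#'   of correlated pairs (default 2).
#' @param tandemRho Target observed correlation of tandem founder/copy
#'   pairs (default 0.9).
#' @param segmentalRhos Target correlations of the segmental pairs
#'   (default c(-0.5, 0)).
#' @param tissues,tissueReplicates,tissueShift Tissue design (default
#'   root/stem/leaf, 3 replicates, +2 log2 member-specific shift).
#' @return Parameter list of class `SimParams`.
#' @export
simParams <- function(seed = 1L, nChromosomes = 5L, nDecoys = 200L,
                      nAP2 = 12L, nRAV = 8L, nDREB = 20L, nERF = 20L,
                      domainMutationRate = 0.05, variantDivergence = 0.25,
                      seedN = 12L, seedMutationRate = 0.15,
                      ap2Length = 60L, b3Length = 50L,
                      proteinLengthRange = c(280L, 450L),
                      isoformFraction = 0.2,
                      tandemSizes = c(3L, 2L),
                      tandemIdentities = c(0.85, 0.80),
                      nSegmental = 2L, segmentalIdentity = 0.80,
                      nAnchorsPerGroup = 5L,
                      stresses = c("cold", "heat", "drought", "salt"),
                      timepoints = c(1, 2, 5, 10, 24),
                      replicates = 4L, noiseSd = 0.5, effectSize = 2,
                      deFraction = 0.4, effectProfileSd = 2,
                      tandemRho = 0.9, segmentalRhos = c(-0.5, 0),
                      tissues = c("root", "stem", "leaf"),
                      tissueReplicates = 3L, tissueShift = 2) {
  stopifnot(nChromosomes >= 1, nDecoys >= 0,
            domainMutationRate >= 0, domainMutationRate <= 1,
            base::length(tandemSizes) == base::length(tandemIdentities),
            replicates >= 1, noiseSd >= 0,
            base::length(segmentalRhos) >= nSegmental)
  structure(as.list(environment()), class = "SimParams")
}

AA20 <- AA_ALPHABET21[1:20]

randomResidues <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# i.i.d. substitutions at the given per-site rate (always to a different
# residue)
mutateResidues <- function(x, rate) {
  if (rate <= 0) return(x)
  v <- strsplit(x, "")[[1]]
  hit <- which(runif(base::length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(AA20, v[i]), 1)
  paste(v, collapse = "")
}

# duplicate a protein and tune the substitution rate by rejection until
# the measured global-alignment identity lands in target +/- tol
tuneIdentityCopy <- function(founder, target, tol = 0.03, maxTries = 60L) {
  p <- 1 - target
  for (k in seq_len(maxTries)) {
    copy <- mutateResidues(founder, p)
    id <- globalAlign(founder, copy)$metrics$identity
    if (abs(id - target) <= tol) {
      return(list(seq = copy, identity = id))
    }
    p <- max(0, min(0.95, p + (id - target)))
  }
  stop("could not attain target identity ", target,
       " under the substitution model")
}

# random exon/intron structure for a CDS of the given length; returns a
# 0-based half-open exon matrix relative to the gene start, plus gene span
randomExonStructure <- function(cdsLen) {
  k <- sample.int(9L, 1)
  while (cdsLen < 30L * k) k <- k - 1L
  cuts <- if (k > 1) sort(sample(seq(30L, cdsLen - 30L), k - 1L)) else integer(0)
  exLens <- diff(c(0L, cuts, cdsLen))
  intLens <- if (k > 1) sample(60:500, k - 1L, replace = TRUE) else integer(0)
  starts <- integer(k); ends <- integer(k)
  pos <- 0L
  for (i in seq_len(k)) {
    starts[i] <- pos
    ends[i] <- pos + exLens[i]
    pos <- ends[i] + if (i < k) intLens[i] else 0L
  }
  cbind(start = starts, end = ends)
}

#' Generate a synthetic annotated proteome with planted family members
#'
#' Produces the full input set for the identification, phylogeny and
#' duplication stages: a proteome with planted domain architectures
#' (2xAP2, AP2+B3, single diverged AP2 variants for DREB and ERF), decoy
#' proteins of pure background, truncated splice isoforms, tandem
#' clusters built by identity-tuned duplication, segmental pairs with
#' intra-species synteny blocks plus cross-species ortholog blocks, seed
#' alignments for profile building, and labelled DREB/ERF anchors.
#' Deterministic for a fixed `params$seed`.
#'
#' @param params A [simParams()] list.
#' @return list with `proteome` (AAStringSet), `annot`
#'   ([GenomeAnnotation-class]), `seeds` (list of gapped `AAStringSet`:
#'   `AP2`, `B3`), `anchors` (data.frame `id`, `label`, `seq`), `blocks`
#'   (synteny data.frame) and `truth` (planted ground truth).
#' @export
genProteomeGff <- function(params = simParams()) {
  withSeed(params$seed, genProteomeGffImpl(params))
}

genProteomeGffImpl <- function(params) {
  L1 <- params$ap2Length; L2 <- params$b3Length
  consAP2 <- randomResidues(L1)
  consB3 <- randomResidues(L2)
  varDREB <- mutateResidues(consAP2, params$variantDivergence)
  varERF <- mutateResidues(consAP2, params$variantDivergence)

  mkSeed <- function(cons, tag) {
    s <- vapply(seq_len(params$seedN), function(i)
      mutateResidues(cons, params$seedMutationRate), character(1))
    out <- Biostrings::AAStringSet(s)
    names(out) <- sprintf("%s_seed_%02d", tag, seq_along(s))
    out
  }
  # seeds mix the base consensus with both subfamily variants so the one
  # AP2 profile detects every architecture
  ap2SeedSeqs <- c(
    vapply(seq_len(params$seedN), function(i)
      mutateResidues(consAP2, params$seedMutationRate), character(1)),
    mutateResidues(varDREB, params$seedMutationRate),
    mutateResidues(varERF, params$seedMutationRate))
  ap2Seed <- Biostrings::AAStringSet(ap2SeedSeqs)
  names(ap2Seed) <- sprintf("AP2_seed_%02d", seq_along(ap2SeedSeqs))
  b3Seed <- mkSeed(consB3, "B3")

  nMembers <- params$nAP2 + params$nRAV + params$nDREB + params$nERF
  subfam <- c(rep("AP2", params$nAP2), rep("RAV", params$nRAV),
              rep("DREB", params$nDREB), rep("ERF", params$nERF))
  nGenes <- nMembers + params$nDecoys
  geneIds <- sprintf("SYNG%04d", seq_len(nGenes))
  memberIds <- geneIds[seq_len(nMembers)]
  decoyIds <- geneIds[(nMembers + 1):nGenes]

  plant <- function(plen, domains) {
    # domains: list of character strings to embed left to right
    prot <- strsplit(randomResidues(plen), "")[[1]]
    offset <- sample(10:40, 1)
    offs <- integer(0)
    for (d in domains) {
      dv <- strsplit(d, "")[[1]]
      prot[offset + seq_along(dv)] <- dv
      offs <- c(offs, offset)  # 0-based
      offset <- offset + base::length(dv) + sample(10:30, 1)
    }
    list(seq = paste(prot, collapse = ""), offsets = offs)
  }

  seqs <- character(nGenes)
  offsets <- vector("list", nGenes)
  nAP2dom <- integer(nGenes); nB3dom <- integer(nGenes)
  for (i in seq_len(nMembers)) {
    plen <- sample(params$proteinLengthRange[1]:params$proteinLengthRange[2], 1)
    doms <- switch(subfam[i],
      AP2 = list(mutateResidues(consAP2, params$domainMutationRate),
                 mutateResidues(consAP2, params$domainMutationRate)),
      RAV = list(mutateResidues(consAP2, params$domainMutationRate),
                 mutateResidues(consB3, params$domainMutationRate)),
      DREB = list(mutateResidues(varDREB, params$domainMutationRate)),
      ERF = list(mutateResidues(varERF, params$domainMutationRate)))
    pl <- plant(plen, doms)
    seqs[i] <- pl$seq
    offsets[[i]] <- pl$offsets
    nAP2dom[i] <- if (subfam[i] == "AP2") 2L else 1L
    nB3dom[i] <- if (subfam[i] == "RAV") 1L else 0L
  }
  for (i in (nMembers + 1):nGenes) {
    seqs[i] <- randomResidues(
      sample(params$proteinLengthRange[1]:params$proteinLengthRange[2], 1))
  }

  # tandem clusters: founder + identity-tuned copies among DREB members,
  # laid out adjacently with 0 or 1 intervening decoys
  drebIdx <- which(subfam == "DREB")
  tandem <- list()
  used <- integer(0)
  for (ci in seq_along(params$tandemSizes)) {
    size <- params$tandemSizes[ci]
    idx <- setdiff(drebIdx, used)[seq_len(size)]
    used <- c(used, idx)
    founder <- seqs[idx[1]]
    realized <- numeric(0)
    for (j in idx[-1]) {
      tc <- tuneIdentityCopy(founder, params$tandemIdentities[ci])
      seqs[j] <- tc$seq
      offsets[[j]] <- offsets[[idx[1]]]
      realized <- c(realized, tc$identity)
    }
    intervening <- sample(0:1, size - 1, replace = TRUE)
    tandem[[ci]] <- list(cluster_id = sprintf("planted_tandem_%d", ci),
                         gene_ids = geneIds[idx],
                         target_identity = params$tandemIdentities[ci],
                         realized_identity = realized,
                         intervening = intervening)
  }

  # layout: tandem clusters move as blocks (with planted intervening
  # decoys inside); everything else is shuffled into chromosomes
  interveningPool <- decoyIds
  units <- list(); usedDecoys <- character(0)
  for (tc in tandem) {
    block <- tc$gene_ids[1]
    for (k in seq_along(tc$intervening)) {
      if (tc$intervening[k] == 1) {
        dv <- setdiff(interveningPool, usedDecoys)[1]
        usedDecoys <- c(usedDecoys, dv)
        block <- c(block, dv)
      }
      block <- c(block, tc$gene_ids[k + 1])
    }
    units[[base::length(units) + 1L]] <- block
  }
  tandemGenes <- unlist(lapply(tandem, `[[`, "gene_ids"))
  loose <- setdiff(geneIds, c(tandemGenes, usedDecoys))
  for (g in sample(loose)) units[[base::length(units) + 1L]] <- g
  units <- sample(units)
  chromOf <- character(nGenes); names(chromOf) <- geneIds
  orderPerChrom <- vector("list", params$nChromosomes)
  for (u in seq_along(units)) {
    ch <- ((u - 1) %% params$nChromosomes) + 1
    orderPerChrom[[ch]] <- c(orderPerChrom[[ch]], units[[u]])
  }

  # segmental pairs: ERF members on different chromosomes, identity-tuned
  erfIdx <- which(subfam == "ERF")
  for (g in geneIds) chromOf[g] <- NA
  for (ch in seq_len(params$nChromosomes)) {
    chromOf[orderPerChrom[[ch]]] <- sprintf("Chr%d", ch)
  }
  segmental <- list()
  segUsed <- integer(0)
  for (si in seq_len(params$nSegmental)) {
    cands <- setdiff(erfIdx, segUsed)
    a <- cands[1]
    b <- cands[which(chromOf[geneIds[cands]] != chromOf[geneIds[a]])[2]]
    segUsed <- c(segUsed, a, b)
    tc <- tuneIdentityCopy(seqs[a], params$segmentalIdentity)
    seqs[b] <- tc$seq
    offsets[[b]] <- offsets[[a]]
    segmental[[si]] <- list(gene_a = geneIds[a], gene_b = geneIds[b],
                            block_id = sprintf("intra_%d", si),
                            realized_identity = tc$identity)
  }

  # coordinates, exon structures, isoforms
  grSeq <- character(0); grStart <- integer(0); grEnd <- integer(0)
  grId <- character(0)
  exonsByTx <- list(); txToGene <- character(0)
  protSeqs <- character(0); protIds <- character(0)
  isoforms <- data.frame(gene_id = character(0), protein_id = character(0),
                         stringsAsFactors = FALSE)
  isoformGenes <- sample(memberIds,
                         round(params$isoformFraction * nMembers))
  for (ch in seq_len(params$nChromosomes)) {
    pos <- 1000L
    for (g in orderPerChrom[[ch]]) {
      i <- match(g, geneIds)
      plen <- nchar(seqs[i])
      ex <- randomExonStructure(3L * plen)
      span <- max(ex[, "end"])
      gStart <- pos
      tx1 <- paste0(g, ".1")
      exonsByTx[[tx1]] <- cbind(start = ex[, "start"] + gStart - 1L,
                                end = ex[, "end"] + gStart - 1L)
      txToGene[tx1] <- g
      protIds <- c(protIds, tx1); protSeqs <- c(protSeqs, seqs[i])
      if (g %in% isoformGenes) {
        tx2 <- paste0(g, ".2")
        keepAa <- floor(0.75 * plen)
        # truncated isoform: single exon over the prefix
        exonsByTx[[tx2]] <- cbind(start = gStart - 1L,
                                  end = gStart - 1L + 3L * keepAa)
        txToGene[tx2] <- g
        protIds <- c(protIds, tx2)
        protSeqs <- c(protSeqs, substr(seqs[i], 1, keepAa))
        isoforms <- rbind(isoforms,
                          data.frame(gene_id = g, protein_id = tx2,
                                     stringsAsFactors = FALSE))
      }
      grId <- c(grId, g); grSeq <- c(grSeq, sprintf("Chr%d", ch))
      grStart <- c(grStart, gStart); grEnd <- c(grEnd, gStart + span - 1L)
      pos <- gStart + span + sample(500:2000, 1)
    }
  }
  genes <- GenomicRanges::GRanges(
    seqnames = grSeq,
    ranges = IRanges::IRanges(start = grStart, end = grEnd),
    strand = sample(c("+", "-"), base::length(grId), replace = TRUE))
  genes$gene_id <- grId
  annot <- new("GenomeAnnotation", genes = genes, exonsByTx = exonsByTx,
               txToGene = txToGene)

  proteome <- Biostrings::AAStringSet(protSeqs)
  names(proteome) <- protIds

  # anchors: fresh draws from the subfamily variants
  anchors <- do.call(rbind, lapply(c("DREB", "ERF"), function(gl) {
    v <- if (gl == "DREB") varDREB else varERF
    data.frame(
      id = sprintf("anchor_%s_%d", gl, seq_len(params$nAnchorsPerGroup)),
      label = gl,
      seq = vapply(seq_len(params$nAnchorsPerGroup), function(i)
        mutateResidues(v, params$domainMutationRate), character(1)),
      stringsAsFactors = FALSE)
  }))

  # synteny blocks: intra-species for segmental pairs + cross-species
  gt <- data.frame(gene_id = grId, chrom = grSeq, start = grStart - 1L,
                   end = grEnd, stringsAsFactors = FALSE)
  blockRows <- list()
  for (sv in segmental) {
    ra <- gt[gt$gene_id == sv$gene_a, ]; rb <- gt[gt$gene_id == sv$gene_b, ]
    blockRows[[base::length(blockRows) + 1L]] <- data.frame(
      block_id = sv$block_id, species_a = "synth", chrom_a = ra$chrom,
      start_a = max(0, ra$start - 5000), end_a = ra$end + 5000,
      gene_a = sv$gene_a, species_b = "synth", chrom_b = rb$chrom,
      start_b = max(0, rb$start - 5000), end_b = rb$end + 5000,
      gene_b = sv$gene_b, stringsAsFactors = FALSE)
  }
  # cross-species blocks: a subset of members gets one ortholog per
  # partner species; the two segmental-pair genes share one ortholog each
  crossSpecies <- c("ricelike", "sorghumlike")
  orthoMembers <- if (nMembers > 0) memberIds[seq(1, nMembers, by = 2)] else
    character(0)
  for (sp in crossSpecies) {
    for (g in orthoMembers) {
      r <- gt[gt$gene_id == g, ]
      blockRows[[base::length(blockRows) + 1L]] <- data.frame(
        block_id = sprintf("%s_%s", sp, g), species_a = "synth",
        chrom_a = r$chrom, start_a = r$start, end_a = r$end, gene_a = g,
        species_b = sp, chrom_b = "c1", start_b = 0, end_b = 1,
        gene_b = sprintf("%s_%s", sp, g), stringsAsFactors = FALSE)
    }
    for (sv in segmental) {
      shared <- sprintf("%s_shared_%s", sp, sv$block_id)
      for (g in c(sv$gene_a, sv$gene_b)) {
        r <- gt[gt$gene_id == g, ]
        blockRows[[base::length(blockRows) + 1L]] <- data.frame(
          block_id = sprintf("%s_%s", sp, g), species_a = "synth",
          chrom_a = r$chrom, start_a = r$start, end_a = r$end, gene_a = g,
          species_b = sp, chrom_b = "c1", start_b = 0, end_b = 1,
          gene_b = shared, stringsAsFactors = FALSE)
      }
    }
  }
  blocks <- do.call(rbind, blockRows)

  truth <- list(
    members = data.frame(
      gene_id = memberIds,
      protein_id = if (nMembers) paste0(memberIds, ".1") else character(0),
      subfamily = subfam, n_AP2 = nAP2dom[seq_len(nMembers)],
      n_B3 = nB3dom[seq_len(nMembers)], stringsAsFactors = FALSE),
    offsets = setNames(offsets[seq_len(nMembers)], memberIds),
    decoys = decoyIds,
    isoforms = isoforms,
    tandem = tandem,
    segmental = segmental,
    consensi = list(AP2 = consAP2, B3 = consB3, DREB = varDREB,
                    ERF = varERF))

  list(proteome = proteome, annot = annot,
       seeds = list(AP2 = ap2Seed, B3 = b3Seed),
       anchors = anchors, blocks = blocks, truth = truth)
}

# solve the latent-mixing weight so the expected observed correlation of
# two fold-change profiles equals the target under the replicate noise:
# observed log2fc = effect + eta, eta ~ N(0, 2 sigma^2 / R), so
# corr_obs = rhoTilde * sigmaE^2 / (sigmaE^2 + 2 sigma^2 / R)
mixingWeight <- function(rho, effectSd, noiseSd, replicates) {
  atten <- effectSd^2 / (effectSd^2 + 2 * noiseSd^2 / replicates)
  rhoTilde <- rho / atten
  if (abs(rhoTilde) > 1) {
    stop("target correlation ", rho,
         " is unattainable under the noise model (required mixing weight ",
         round(rhoTilde, 3), ")")
  }
  rhoTilde
}

#' Generate synthetic stress and tissue expression data
#'
#' Baseline log2 abundances are Normal(5, 1); stress samples add planted
#' per-(gene, stress, timepoint) effects; replicate noise is
#' Normal(0, noiseSd). Duplicate pairs with a target correlation rho get
#' effect profiles built by latent mixing,
#' `effect_b = rhoTilde * latent_a + sqrt(1 - rhoTilde^2) * latent_b`,
#' with `rhoTilde` solved so the expected observed fold-change correlation
#' equals rho under the noise (see the methods vignette). Tissue samples
#' (RNA-seq-like counts, `round(2^x)`) give each member a shifted
#' preferred tissue. Deterministic given `seed`.
#'
#' @param params A [simParams()] list.
#' @param truth Truth list from [genProteomeGff()] (only `members`,
#'   `decoys`, `tandem` and `segmental` are used, so a minimal list
#'   works).
#' @param seed RNG seed (default `params$seed + 1000`).
#' @return list with `stress` (SummarizedExperiment, intensities),
#'   `tissue` (SummarizedExperiment, counts) and `truth` updated with
#'   `deEffects` and `pairCorrelations`.
#' @export
genExpression <- function(params, truth, seed = params$seed + 1000L) {
  withSeed(seed, genExpressionImpl(params, truth))
}

genExpressionImpl <- function(params, truth) {
  geneIds <- c(truth$members$gene_id, truth$decoys)
  G <- base::length(geneIds)
  R <- params$replicates
  grid <- expand.grid(stress = params$stresses,
                      timepoint = params$timepoints,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$stress, grid$timepoint), ]
  C <- nrow(grid)

  # correlated duplicate pairs via latent mixing
  pairRows <- list()
  if (base::length(truth$tandem) && params$deFraction > 0) {
    for (tc in truth$tandem) {
      for (k in 2:base::length(tc$gene_ids)) {
        pairRows[[base::length(pairRows) + 1L]] <-
          data.frame(gene_a = tc$gene_ids[1], gene_b = tc$gene_ids[k],
                     rho = params$tandemRho, stringsAsFactors = FALSE)
      }
    }
  }
  if (base::length(truth$segmental) && params$deFraction > 0) {
    for (si in seq_along(truth$segmental)) {
      sv <- truth$segmental[[si]]
      pairRows[[base::length(pairRows) + 1L]] <-
        data.frame(gene_a = sv$gene_a, gene_b = sv$gene_b,
                   rho = params$segmentalRhos[si], stringsAsFactors = FALSE)
    }
  }
  pairs <- if (base::length(pairRows)) do.call(rbind, pairRows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               rho = numeric(0))

  effects <- matrix(0, G, C, dimnames = list(geneIds, NULL))
  latentOf <- list()
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (is.null(latentOf[[ga]])) {
      latentOf[[ga]] <- rnorm(C, 0, params$effectProfileSd)
      effects[ga, ] <- latentOf[[ga]]
    }
    rhoTilde <- mixingWeight(pairs$rho[i], params$effectProfileSd,
                             params$noiseSd, R)
    own <- rnorm(C, 0, params$effectProfileSd)
    effects[gb, ] <- rhoTilde * latentOf[[ga]] +
      sqrt(1 - rhoTilde^2) * own
  }

  # plain DE effects on a fraction of the remaining members
  pairGenes <- unique(c(pairs$gene_a, pairs$gene_b))
  free <- setdiff(truth$members$gene_id, pairGenes)
  nDE <- round(params$deFraction * base::length(free))
  deGenes <- if (nDE > 0) sample(free, nDE) else character(0)
  deRows <- list()
  for (g in deGenes) {
    st <- sample(params$stresses, 1)
    sign <- sample(c(-1, 1), 1)
    cols <- which(grid$stress == st)
    effects[g, cols] <- sign * params$effectSize
    deRows[[base::length(deRows) + 1L]] <- data.frame(
      gene_id = g, stress = st, timepoint = grid$timepoint[cols],
      effect = sign * params$effectSize, stringsAsFactors = FALSE)
  }

  baseline <- rnorm(G, 5, 1)
  sampleIds <- character(0); condMeta <- list()
  vals <- NULL
  for (k in seq_len(C)) {
    for (r in seq_len(R)) {
      x <- baseline + effects[, k] + rnorm(G, 0, params$noiseSd)
      vals <- cbind(vals, 2^x)
      sampleIds <- c(sampleIds,
                     sprintf("%s_%gh_rep%d", grid$stress[k],
                             grid$timepoint[k], r))
      condMeta[[base::length(condMeta) + 1L]] <-
        data.frame(condition = grid$stress[k],
                   timepoint_hours = grid$timepoint[k], replicate = r)
    }
  }
  for (t in params$timepoints) {
    for (r in seq_len(R)) {
      x <- baseline + rnorm(G, 0, params$noiseSd)
      vals <- cbind(vals, 2^x)
      sampleIds <- c(sampleIds, sprintf("control_%gh_rep%d", t, r))
      condMeta[[base::length(condMeta) + 1L]] <-
        data.frame(condition = "control", timepoint_hours = t, replicate = r)
    }
  }
  meta <- do.call(rbind, condMeta)
  meta <- data.frame(sample_id = sampleIds, meta, stringsAsFactors = FALSE)
  rownames(vals) <- geneIds; colnames(vals) <- sampleIds
  stressSe <- SummarizedExperiment::SummarizedExperiment(
    assays = list(value = vals),
    colData = S4Vectors::DataFrame(meta, row.names = sampleIds))
  S4Vectors::metadata(stressSe)$units <- "intensity"

  # tissue counts
  shiftTissue <- sample(params$tissues, nrow(truth$members), replace = TRUE)
  tvals <- NULL; tIds <- character(0); tMeta <- list()
  for (t in params$tissues) {
    shift <- numeric(G)
    shift[match(truth$members$gene_id[shiftTissue == t], geneIds)] <-
      params$tissueShift
    for (r in seq_len(params$tissueReplicates)) {
      x <- baseline + shift + rnorm(G, 0, params$noiseSd)
      tvals <- cbind(tvals, round(2^x))
      tIds <- c(tIds, sprintf("%s_rep%d", t, r))
      tMeta[[base::length(tMeta) + 1L]] <-
        data.frame(condition = t, timepoint_hours = NA_real_, replicate = r)
    }
  }
  tm <- do.call(rbind, tMeta)
  tm <- data.frame(sample_id = tIds, tm, stringsAsFactors = FALSE)
  rownames(tvals) <- geneIds; colnames(tvals) <- tIds
  tissueSe <- SummarizedExperiment::SummarizedExperiment(
    assays = list(value = tvals),
    colData = S4Vectors::DataFrame(tm, row.names = tIds))
  S4Vectors::metadata(tissueSe)$units <- "counts"

  truth$deEffects <- if (base::length(deRows)) do.call(rbind, deRows) else
    data.frame(gene_id = character(0), stress = character(0),
               timepoint = numeric(0), effect = numeric(0))
  truth$pairCorrelations <- pairs
  truth$effectMatrix <- effects
  truth$preferredTissue <- setNames(shiftTissue, truth$members$gene_id)
  list(stress = stressSe, tissue = tissueSe, truth = truth)
}

#' Generate a synthetic probe-alignment table
#'
#' Four probes per gene: one perfectly mapped exonic probe (retained by
#' [probeFilter()]) plus planted failures (mismatched, multi-hit,
#' intronic) for a random subset. Deterministic given the seed.
#'
#' @param geneIds Character vector of target genes.
#' @param seed RNG seed.
#' @return data.frame in [readProbeTable()] layout.
#' @export
genProbeTable <- function(geneIds, seed = 1L) {
  withSeed(seed, {
    rows <- lapply(seq_along(geneIds), function(i) {
      g <- geneIds[i]
      out <- data.frame(
        probe_id = sprintf("%s_p1", g), gene_id = g, mismatches = 0L,
        n_genomic_hits = 1L, in_exon = TRUE, stringsAsFactors = FALSE)
      if (runif(1) < 0.3) {
        out <- rbind(out, data.frame(
          probe_id = sprintf("%s_p2", g), gene_id = g,
          mismatches = sample(1:2, 1), n_genomic_hits = 1L, in_exon = TRUE))
      }
      if (runif(1) < 0.3) {
        out <- rbind(out, data.frame(
          probe_id = sprintf("%s_p3", g), gene_id = g, mismatches = 0L,
          n_genomic_hits = 2L, in_exon = TRUE))
      }
      if (runif(1) < 0.3) {
        out <- rbind(out, data.frame(
          probe_id = sprintf("%s_p4", g), gene_id = g, mismatches = 0L,
          n_genomic_hits = 1L, in_exon = FALSE))
      }
      out
    })
    do.call(rbind, rows)
  })
}
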