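#' Build a pipeline configuration
#'
#' Collects paths, stage parameters and seeds into one validated list.
#' Every default equals the corresponding module default, so an empty
#' config runs the documented defaults. Configs can also be loaded from a
#' YAML file with [readPipelineConfig()]; values given there override the
#' defaults and CLI-style overrides passed to `pipelineConfig()` override
#' both.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed; all stage seeds derive from it.
#' @param speciesPrefix Prefix for assigned names (default `"Syn"`).
#' @param paths Named list of input paths; for simulated runs these
#'   default to the simulate stage's outputs inside `outdir`.
#' @param simulate,identify,duplication,expression,divergence Named lists
#'   of overrides for [simParams()], [identifyParams()], [dupParams()],
#'   [deParams()], [divergenceParams()].
#' @param phylogeny list with `B` (bootstrap replicates, default 200 for
#'   pipeline runs), `model` (distance model, default "p").
#' @return Config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outdir, seed = 1L, speciesPrefix = "Syn",
                           paths = list(), simulate = list(),
                           identify = list(), duplication = list(),
                           expression = list(), divergence = list(),
                           phylogeny = list()) {
  ph <- modifyList(list(B = 200L, model = "p"), phylogeny)
  defaultPaths <- list(
    proteome = file.path(outdir, "proteome.fasta"),
    gff = file.path(outdir, "annotation.gff3"),
    ap2_seed = file.path(outdir, "ap2_seed.fasta"),
    b3_seed = file.path(outdir, "b3_seed.fasta"),
    anchors = file.path(outdir, "anchors.fasta"),
    synteny = file.path(outdir, "synteny_blocks.tsv"),
    stress_matrix = file.path(outdir, "stress_matrix.tsv"),
    stress_metadata = file.path(outdir, "stress_metadata.tsv"),
    tissue_matrix = file.path(outdir, "tissue_counts.tsv"),
    tissue_metadata = file.path(outdir, "tissue_metadata.tsv"),
    probes = file.path(outdir, "probes.tsv"))
  structure(list(
    outdir = outdir, seed = as.integer(seed),
    speciesPrefix = speciesPrefix,
    paths = modifyList(defaultPaths, paths),
    simulate = simulate, identify = identify, duplication = duplication,
    expression = expression, divergence = divergence, phylogeny = ph),
    class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipelineConfig()]
#'   fields; `outdir` is required.
#' @param ... Overrides applied on top of the file.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (is.null(y$outdir)) stop("config must set outdir")
  args <- modifyList(y, list(...))
  do.call(pipelineConfig, args)
}

stagePrereq <- function(config, files, neededBy, runFirst) {
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("stage '", neededBy, "' is missing upstream artifact(s): ",
         paste(basename(missing), collapse = ", "),
         "; run stage '", runFirst, "' first")
  }
}

writeManifest <- function(config, stage, artifacts) {
  cfgJson <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null")
  tmp <- file.path(config$outdir, ".config.json")
  writeLines(cfgJson, tmp)
  manifest <- list(
    tool = "ap2erf",
    version = as.character(utils::packageVersion("ap2erf")),
    stage = stage,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(tmp)),
    artifacts = basename(artifacts))
  jsonlite::write_json(manifest,
                       file.path(config$outdir,
                                 sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

pipeLog <- function(...) message("[ap2erf] ", ...)

#' Run pipeline stages
#'
#' Orchestrates the full analysis behind per-stage TSV/Newick artifacts
#' in `config$outdir`. Stages: `simulate` (synthetic study generation),
#' `identify` (profiles, candidate collection, isoform collapse,
#' exclusion filter, architecture classification), `classify` (subfamily
#' summary), `phylo` (anchored MSA, bootstrap NJ tree, group labels,
#' final names), `duplicate` (tandem/segmental events + orthologs),
#' `express` (stress DE + tissue profile + probe filter), `diverge`
#' (duplicate-pair divergence), or `all` in dependency order. Each stage
#' writes a manifest with the config hash so identical config + seeds
#' reproduce byte-identical artifacts.
#'
#' @param stage One of the stage names above.
#' @param config A [pipelineConfig()] list.
#' @return Named list of artifact paths, invisibly.
#' @export
runPipeline <- function(stage = c("all", "simulate", "identify", "classify",
                                  "phylo", "duplicate", "express", "diverge"),
                        config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "identify", "classify", "phylo", "duplicate", "express",
      "diverge")
  } else stage
  out <- list()
  for (s in stages) {
    pipeLog("stage ", s, " started")
    out[[s]] <- switch(s,
      simulate = stageSimulate(config),
      identify = stageIdentify(config),
      classify = stageClassify(config),
      phylo = stagePhylo(config),
      duplicate = stageDuplicate(config),
      express = stageExpress(config),
      diverge = stageDiverge(config))
    pipeLog("stage ", s, " done")
  }
  invisible(out)
}

stageSimulate <- function(config) {
  params <- do.call(simParams, modifyList(list(seed = config$seed),
                                          config$simulate))
  gen <- genProteomeGff(params)
  expr <- genExpression(params, gen$truth)
  p <- config$paths
  writeProteinFasta(gen$proteome, p$proteome)
  writeGff3(gen$annot, p$gff)
  writeProteinFasta(gen$seeds$AP2, p$ap2_seed)
  writeProteinFasta(gen$seeds$B3, p$b3_seed)
  anchorSet <- Biostrings::AAStringSet(gen$anchors$seq)
  names(anchorSet) <- sprintf("%s group=%s", gen$anchors$id,
                              gen$anchors$label)
  Biostrings::writeXStringSet(anchorSet, p$anchors)
  writeTsv(gen$blocks, p$synteny)
  writeExpressionTable(expr$stress, p$stress_matrix, p$stress_metadata)
  writeExpressionTable(expr$tissue, p$tissue_matrix, p$tissue_metadata)
  probes <- genProbeTable(geneTable(gen$annot)$gene_id,
                          seed = config$seed + 5L)
  writeTsv(probes, p$probes)
  truthMembers <- file.path(config$outdir, "truth_members.tsv")
  writeTsv(expr$truth$members, truthMembers)
  truthPairs <- file.path(config$outdir, "truth_pairs.tsv")
  writeTsv(expr$truth$pairCorrelations, truthPairs)
  arts <- c(unlist(p), truthMembers, truthPairs)
  writeManifest(config, "simulate", arts)
  arts
}

# read the anchors FASTA; group labels live in a "group=" header tag
readAnchors <- function(path) {
  a <- readProteinFasta(path)
  desc <- S4Vectors::mcols(a)$description
  label <- sub("^.*group=(\\S+).*$", "\\1", desc)
  if (any(!nzchar(label))) stop("anchor header(s) missing group= tag")
  data.frame(id = names(a), label = label, seq = as.character(a),
             stringsAsFactors = FALSE)
}

buildCalibratedProfiles <- function(config, proteome) {
  meanLen <- max(50L, as.integer(round(mean(Biostrings::width(proteome)))))
  ap2 <- buildProfile(readProteinFasta(config$paths$ap2_seed, gapped = TRUE),
                      "AP2")
  b3 <- buildProfile(readProteinFasta(config$paths$b3_seed, gapped = TRUE),
                     "B3")
  list(
    calibrateNull(ap2, nShuffles = 500L, length = meanLen,
                  seed = config$seed + 11L),
    calibrateNull(b3, nShuffles = 500L, length = meanLen,
                  seed = config$seed + 12L))
}

stageIdentify <- function(config) {
  p <- config$paths
  stagePrereq(config, c(p$proteome, p$gff, p$ap2_seed, p$b3_seed, p$anchors),
              "identify", "simulate")
  proteome <- readProteinFasta(p$proteome)
  annot <- readGenomeAnnotation(p$gff)
  profiles <- buildCalibratedProfiles(config, proteome)
  anchors <- readAnchors(p$anchors)
  params <- do.call(identifyParams, config$identify)
  res <- identifyFamily(proteome, profiles,
                        setNames(anchors$seq, anchors$id), annot, params)
  membersPath <- file.path(config$outdir, "members.tsv")
  writeTsv(res$members, membersPath)
  exclusionsPath <- file.path(config$outdir, "exclusions.tsv")
  writeTsv(res$exclusions, exclusionsPath)
  hitsPath <- file.path(config$outdir, "hits.tsv")
  writeTsv(res$hits, hitsPath)
  prof1 <- file.path(config$outdir, "profile_AP2.tsv")
  prof2 <- file.path(config$outdir, "profile_B3.tsv")
  writeProfileTsv(profiles[[1]], prof1)
  writeProfileTsv(profiles[[2]], prof2)
  arts <- c(membersPath, exclusionsPath, hitsPath, prof1, prof2)
  writeManifest(config, "identify", arts)
  arts
}

stageClassify <- function(config) {
  membersPath <- file.path(config$outdir, "members.tsv")
  stagePrereq(config, membersPath, "classify", "identify")
  members <- readTsv(membersPath)
  counts <- as.data.frame(table(members$subfamily),
                          stringsAsFactors = FALSE)
  colnames(counts) <- c("subfamily", "n_genes")
  outPath <- file.path(config$outdir, "subfamily_counts.tsv")
  writeTsv(counts, outPath)
  writeManifest(config, "classify", outPath)
  outPath
}

stagePhylo <- function(config) {
  p <- config$paths
  membersPath <- file.path(config$outdir, "members.tsv")
  hitsPath <- file.path(config$outdir, "hits.tsv")
  profPath <- file.path(config$outdir, "profile_AP2.tsv")
  stagePrereq(config, c(membersPath, hitsPath, profPath), "phylo", "identify")
  members <- readTsv(membersPath)
  hits <- readTsv(hitsPath)
  profile <- readProfileTsv(profPath)
  proteome <- readProteinFasta(p$proteome)
  anchors <- readAnchors(p$anchors)

  domSeqs <- bestDomainSubsequences(members, hits, proteome,
                                    domainName(profile))
  allSeqs <- c(domSeqs, setNames(anchors$seq, anchors$id))
  msa <- anchorMSA(profile, allSeqs)
  tree <- bootstrapSupport(msa, B = config$phylogeny$B,
                           seed = config$seed + 21L,
                           model = config$phylogeny$model)
  treePath <- file.path(config$outdir, "tree.nwk")
  writeNewickTree(tree, treePath)
  labels <- labelGroups(tree, setNames(anchors$label, anchors$id))
  groupsPath <- file.path(config$outdir, "groups.tsv")
  writeTsv(data.frame(member_id = names(labels), group = unname(labels),
                      stringsAsFactors = FALSE), groupsPath)

  unresolved <- members$subfamily == "DREB_ERF_unresolved"
  resolved <- labels[members$protein_id[unresolved]]
  members$subfamily[unresolved] <- ifelse(
    resolved %in% c("DREB", "ERF"), resolved, "ERF_unplaced")
  unplaced <- members$subfamily == "ERF_unplaced"
  if (any(unplaced)) {
    warning(sum(unplaced), " member(s) not classifiable from anchors; ",
            "left out of naming")
  }
  named <- assignNames(members[!unplaced, , drop = FALSE],
                       config$speciesPrefix)
  namedPath <- file.path(config$outdir, "members_named.tsv")
  writeTsv(named, namedPath)
  arts <- c(treePath, groupsPath, namedPath)
  writeManifest(config, "phylo", arts)
  arts
}

#' Best family-domain subsequence per member
#'
#' Cuts, for each member, the highest-scoring family-domain hit region
#' from its protein.
#'
#' @param members,hits data.frames from the identify stage.
#' @param proteome Named `AAStringSet`.
#' @param famDomain Domain name (default `"AP2"`).
#' @return Named character vector protein id -> subsequence.
#' @export
bestDomainSubsequences <- function(members, hits, proteome,
                                   famDomain = "AP2") {
  seqs <- as.character(proteome)
  out <- character(0)
  for (pid in members$protein_id) {
    h <- hits[hits$protein_id == pid & hits$domain == famDomain, ,
              drop = FALSE]
    if (!nrow(h)) next
    best <- h[which.max(h$score), ]
    out[pid] <- substr(seqs[[pid]], best$start + 1L, best$end)
  }
  out
}

stageDuplicate <- function(config) {
  p <- config$paths
  namedPath <- file.path(config$outdir, "members_named.tsv")
  stagePrereq(config, namedPath, "duplicate", "phylo")
  stagePrereq(config, c(p$proteome, p$gff, p$synteny), "duplicate",
              "simulate")
  members <- readTsv(namedPath)
  proteome <- readProteinFasta(p$proteome)
  annot <- readGenomeAnnotation(p$gff)
  blocks <- readSyntenyBlocks(p$synteny)
  geneOrder <- geneOrderFromAnnotation(annot)
  arts <- character(0)
  for (mode in c("stringent", "relaxed")) {
    params <- do.call(dupParams,
                      modifyList(list(mode = mode), config$duplication))
    tand <- tandemClusters(members, proteome, geneOrder, params)
    seg <- segmentalPairs(members, proteome, blocks, params, tand)
    evPath <- file.path(config$outdir,
                        sprintf("duplication_events_%s.tsv", mode))
    writeTsv(duplicationTable(c(tand, seg)), evPath)
    arts <- c(arts, evPath)
  }
  orth <- mapOrthologs(members, blocks, focalSpecies = "synth")
  orthPath <- file.path(config$outdir, "orthologs.tsv")
  writeTsv(orth$table, orthPath)
  orthSummaryPath <- file.path(config$outdir, "ortholog_summary.tsv")
  writeTsv(orth$summary, orthSummaryPath)
  arts <- c(arts, orthPath, orthSummaryPath)
  writeManifest(config, "duplicate", arts)
  arts
}

stageExpress <- function(config) {
  p <- config$paths
  stagePrereq(config, c(p$stress_matrix, p$stress_metadata), "express",
              "simulate")
  params <- do.call(deParams,
                    modifyList(list(seed = config$seed + 31L),
                               config$expression))
  se <- readExpressionTable(p$stress_matrix, p$stress_metadata,
                            units = "intensity")
  de <- stressDE(se, params)
  arts <- character(0)
  for (a in c("log2fc", "qvalue", "call")) {
    m <- SummarizedExperiment::assay(de, a)
    path <- file.path(config$outdir, sprintf("stress_%s.tsv", a))
    writeTsv(data.frame(gene_id = rownames(m), m, check.names = FALSE),
             path)
    arts <- c(arts, path)
  }
  if (file.exists(p$tissue_matrix)) {
    tis <- readExpressionTable(p$tissue_matrix, p$tissue_metadata,
                               units = "counts")
    annot <- readGenomeAnnotation(p$gff)
    rpkm <- computeRpkm(tis, exonLengthsFromAnnotation(annot))
    namedPath <- file.path(config$outdir, "members_named.tsv")
    memberGenes <- if (file.exists(namedPath)) {
      readTsv(namedPath)$gene_id
    } else rownames(SummarizedExperiment::assay(rpkm, "value"))
    prof <- tissueProfile(rpkm, memberGenes)
    profPath <- file.path(config$outdir, "tissue_profile.tsv")
    writeTsv(data.frame(gene_id = rownames(prof), prof, check.names = FALSE),
             profPath)
    arts <- c(arts, profPath)
  }
  if (file.exists(p$probes)) {
    kept <- probeFilter(readProbeTable(p$probes))
    keptPath <- file.path(config$outdir, "probes_retained.tsv")
    writeTsv(kept, keptPath)
    arts <- c(arts, keptPath)
  }
  writeManifest(config, "express", arts)
  arts
}

stageDiverge <- function(config) {
  evPath <- file.path(config$outdir, "duplication_events_stringent.tsv")
  fcPath <- file.path(config$outdir, "stress_log2fc.tsv")
  stagePrereq(config, evPath, "diverge", "duplicate")
  stagePrereq(config, fcPath, "diverge", "express")
  events <- readTsv(evPath)
  fcTab <- readTsv(fcPath)
  fc <- as.matrix(fcTab[, -1, drop = FALSE])
  rownames(fc) <- fcTab$gene_id
  params <- do.call(divergenceParams, config$divergence)
  pairs <- unique(events[, c("gene_a", "gene_b")])
  div <- classifyDivergence(pairs, fc, params)
  divPath <- file.path(config$outdir, "divergence.tsv")
  writeTsv(div, divPath)
  writeManifest(config, "diverge", divPath)
  divPath
}
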