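#' Parameters for duplication detection
#'
#' Stringent mode (similarity >= 0.70, coverage >= 0.80) stands in for the
#' restrictive criteria of classical duplication surveys; relaxed mode uses
#' the published looser thresholds of >= 40% similarity over >= 60%
#' matching length. Tandem adjacency allows at most `maxIntervening`
#' non-family genes between cluster members (default 1).
#'
#' @param mode `"stringent"` or `"relaxed"`.
#' @param minSimilarity,minCoverage Override the mode defaults.
#' @param maxIntervening Maximum intervening genes for tandem adjacency.
#' @param metric Which alignment metric the similarity threshold applies
#'   to: `"similarity"` (positive-substitution fraction, default) or
#'   `"identity"`.
#' @return Parameter list of class `DupParams`.
#' @export
dupParams <- function(mode = c("stringent", "relaxed"),
                      minSimilarity = NULL, minCoverage = NULL,
                      maxIntervening = 1L,
                      metric = c("similarity", "identity")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  defaults <- list(stringent = c(0.70, 0.80), relaxed = c(0.40, 0.60))[[mode]]
  if (is.null(minSimilarity)) minSimilarity <- defaults[1]
  if (is.null(minCoverage)) minCoverage <- defaults[2]
  stopifnot(minSimilarity > 0, minSimilarity <= 1,
            minCoverage > 0, minCoverage <= 1, maxIntervening >= 0)
  structure(list(mode = mode, minSimilarity = minSimilarity,
                 minCoverage = minCoverage,
                 maxIntervening = as.integer(maxIntervening),
                 metric = metric),
            class = "DupParams")
}

# pairwise metrics between two member proteins, threshold check
pairPasses <- function(a, b, params) {
  m <- globalAlign(a, b)$metrics
  passed <- m[[params$metric]] >= params$minSimilarity &&
    m$coverage >= params$minCoverage
  list(passes = passed, metrics = m)
}

#' Detect tandem duplication clusters
#'
#' Builds a graph over family members with an edge between two members
#' when they lie on the same chromosome with at most `maxIntervening`
#' genes between them in the full annotation's gene order, and their
#' global alignment passes the similarity and coverage thresholds.
#' Connected components of size >= 2 are reported as tandem clusters with
#' per-edge alignment metrics.
#'
#' @param members Member data.frame with `gene_id`, `protein_id`, `chrom`.
#' @param proteome Named `AAStringSet` containing the member proteins.
#' @param geneOrder Named list: chromosome -> character vector of all gene
#'   ids in positional order (the full annotation, not just family
#'   members); from [geneOrderFromAnnotation()].
#' @param params A [dupParams()] list.
#' @return list of events; each has `kind = "tandem"`, `cluster_id`,
#'   `gene_ids`, `chrom`, and `pairs` (data.frame of edge metrics).
#' @export
tandemClusters <- function(members, proteome, geneOrder, params = dupParams()) {
  missing <- vapply(seq_len(nrow(members)), function(i) {
    !(members$gene_id[i] %in% geneOrder[[members$chrom[i]]])
  }, logical(1))
  if (any(missing)) {
    stop("member gene(s) absent from the gene order: ",
         paste(members$gene_id[missing], collapse = ", "))
  }
  n <- nrow(members)
  pos <- vapply(seq_len(n), function(i) {
    match(members$gene_id[i], geneOrder[[members$chrom[i]]])
  }, integer(1))
  seqs <- as.character(proteome)[match(members$protein_id, names(proteome))]
  adj <- matrix(FALSE, n, n)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (members$chrom[i] != members$chrom[j]) next
      intervening <- abs(pos[i] - pos[j]) - 1L
      if (intervening > params$maxIntervening) next
      pp <- pairPasses(seqs[i], seqs[j], params)
      if (!pp$passes) next
      adj[i, j] <- adj[j, i] <- TRUE
      edges[[base::length(edges) + 1L]] <- cbind(
        data.frame(gene_a = members$gene_id[i], gene_b = members$gene_id[j],
                   intervening = intervening, stringsAsFactors = FALSE),
        pp$metrics)
    }
  }
  comp <- connectedComponents(adj)
  edgeDf <- if (base::length(edges)) do.call(rbind, edges) else NULL
  events <- list()
  cid <- 0L
  for (cc in comp) {
    if (base::length(cc) < 2) next
    cid <- cid + 1L
    gids <- members$gene_id[cc]
    events[[cid]] <- list(
      kind = "tandem",
      cluster_id = sprintf("tandem_%02d", cid),
      gene_ids = gids[order(pos[cc])],
      chrom = members$chrom[cc[1]],
      pairs = edgeDf[edgeDf$gene_a %in% gids & edgeDf$gene_b %in% gids, ,
                     drop = FALSE])
  }
  events
}

connectedComponents <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    stack <- s; comp <- integer(0)
    while (base::length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, which(adj[v, ] & !seen))
    }
    comps[[base::length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Extract per-chromosome gene order from an annotation
#'
#' @param annot A [GenomeAnnotation-class].
#' @return Named list: chromosome -> gene ids sorted by start coordinate.
#' @export
geneOrderFromAnnotation <- function(annot) {
  gt <- geneTable(annot)
  gt <- gt[order(gt$chrom, gt$start), ]
  split(gt$gene_id, gt$chrom)
}

#' Detect segmental duplication pairs via intra-species synteny blocks
#'
#' A member pair is reported segmental when both genes are anchors of (or
#' fall inside the two regions of) one intra-species synteny block, their
#' global alignment passes the thresholds, and they are not already
#' together in a tandem cluster.
#'
#' @param members Member data.frame (`gene_id`, `protein_id`, `chrom`,
#'   `start`, `end`).
#' @param proteome Named `AAStringSet`.
#' @param blocks Synteny-block data.frame ([readSyntenyBlocks()]); only
#'   rows with `species_a == species_b` are used.
#' @param params A [dupParams()] list.
#' @param tandemEvents Output of [tandemClusters()] used for the
#'   exclusivity rule.
#' @return list of events (`kind = "segmental"`, `gene_ids`, `block_id`,
#'   `pairs`).
#' @export
segmentalPairs <- function(members, proteome, blocks, params = dupParams(),
                           tandemEvents = list()) {
  intra <- blocks[blocks$species_a == blocks$species_b, , drop = FALSE]
  if (!nrow(intra)) return(list())
  tandemSets <- lapply(tandemEvents, `[[`, "gene_ids")
  inSameTandem <- function(a, b) {
    any(vapply(tandemSets, function(s) a %in% s && b %in% s, logical(1)))
  }
  memberGene <- members$gene_id
  seqs <- as.character(proteome)[match(members$protein_id, names(proteome))]
  names(seqs) <- memberGene
  inRegion <- function(g, chrom, lo, hi) {
    i <- match(g, memberGene)
    members$chrom[i] == chrom && members$start[i] >= lo && members$end[i] <= hi
  }
  events <- list()
  seenPair <- character(0)
  for (bid in unique(intra$block_id)) {
    rows <- intra[intra$block_id == bid, , drop = FALSE]
    anchorsA <- unique(rows$gene_a); anchorsB <- unique(rows$gene_b)
    regA <- c(rows$chrom_a[1], min(rows$start_a), max(rows$end_a))
    regB <- c(rows$chrom_b[1], min(rows$start_b), max(rows$end_b))
    sideA <- memberGene[memberGene %in% anchorsA |
      vapply(memberGene, inRegion, logical(1), chrom = regA[1],
             lo = as.numeric(regA[2]), hi = as.numeric(regA[3]))]
    sideB <- memberGene[memberGene %in% anchorsB |
      vapply(memberGene, inRegion, logical(1), chrom = regB[1],
             lo = as.numeric(regB[2]), hi = as.numeric(regB[3]))]
    for (ga in sideA) for (gb in sideB) {
      if (ga == gb) next
      key <- paste(sort(c(ga, gb)), collapse = "|")
      if (key %in% seenPair) next
      if (inSameTandem(ga, gb)) next
      pp <- pairPasses(seqs[[ga]], seqs[[gb]], params)
      if (!pp$passes) next
      seenPair <- c(seenPair, key)
      events[[base::length(events) + 1L]] <- list(
        kind = "segmental",
        cluster_id = sprintf("segmental_%02d", base::length(events) + 1L),
        gene_ids = sort(c(ga, gb)),
        chrom = members$chrom[match(c(ga, gb), memberGene)],
        block_id = bid,
        pairs = cbind(data.frame(gene_a = ga, gene_b = gb,
                                 stringsAsFactors = FALSE), pp$metrics))
    }
  }
  events
}

#' Map members to cross-species orthologs via synteny blocks
#'
#' Every cross-species block anchoring a member yields one ortholog row;
#' members with no anchoring block are absent from the table.
#'
#' @param members Member data.frame with `gene_id`.
#' @param blocks Synteny-block data.frame; rows with
#'   `species_a != species_b` are used, with the focal species on side a
#'   (rows where it appears on side b are flipped automatically when
#'   `focalSpecies` is given).
#' @param focalSpecies Optional focal species name.
#' @return list with `table` (data.frame `member_gene`, `species`,
#'   `ortholog`, `block_id`) and `summary` (ortholog-bearing member count
#'   per species).
#' @export
mapOrthologs <- function(members, blocks, focalSpecies = NULL) {
  cross <- blocks[blocks$species_a != blocks$species_b, , drop = FALSE]
  if (!is.null(focalSpecies)) {
    flip <- cross$species_b == focalSpecies
    if (any(flip)) {
      f <- cross[flip, ]
      cross[flip, c("species_a", "chrom_a", "start_a", "end_a", "gene_a",
                    "species_b", "chrom_b", "start_b", "end_b", "gene_b")] <-
        f[, c("species_b", "chrom_b", "start_b", "end_b", "gene_b",
              "species_a", "chrom_a", "start_a", "end_a", "gene_a")]
    }
    cross <- cross[cross$species_a == focalSpecies, , drop = FALSE]
  }
  hit <- cross[cross$gene_a %in% members$gene_id, , drop = FALSE]
  tab <- data.frame(member_gene = hit$gene_a, species = hit$species_b,
                    ortholog = hit$gene_b, block_id = hit$block_id,
                    stringsAsFactors = FALSE)
  tab <- unique(tab)
  summary <- if (nrow(tab)) {
    counts <- tapply(tab$member_gene, tab$species,
                     function(x) base::length(unique(x)))
    data.frame(species = names(counts), n_members_with_ortholog =
                 as.integer(counts), stringsAsFactors = FALSE)
  } else {
    data.frame(species = character(0), n_members_with_ortholog = integer(0))
  }
  list(table = tab, summary = summary)
}

#' Flatten duplication events to a table
#'
#' @param events list of events from [tandemClusters()] /
#'   [segmentalPairs()].
#' @return data.frame, one row per event pair.
#' @export
duplicationTable <- function(events) {
  if (!base::length(events)) {
    return(data.frame(kind = character(0), cluster_id = character(0),
                      gene_a = character(0), gene_b = character(0),
                      chrom = character(0), identity = numeric(0),
                      similarity = numeric(0), coverage = numeric(0),
                      block_id = character(0)))
  }
  do.call(rbind, lapply(events, function(ev) {
    p <- ev$pairs
    data.frame(kind = ev$kind, cluster_id = ev$cluster_id,
               gene_a = p$gene_a, gene_b = p$gene_b,
               chrom = paste(unique(ev$chrom), collapse = ","),
               identity = p$identity, similarity = p$similarity,
               coverage = p$coverage,
               block_id = if (!is.null(ev$block_id)) ev$block_id else NA,
               stringsAsFactors = FALSE)
  }))
}
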