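#' Parameters for stress differential-expression calling
#'
#' @param fcThreshold Log2 fold-change threshold; a call requires
#'   `|log2fc|` above it (default 1).
#' @param qMax q-value cutoff for significance (default 0.05).
#' @param nPermutations Label permutations per condition (default 1000;
#'   when the number of distinct balanced label splits is smaller, all are
#'   enumerated exactly).
#' @param s0 SAM fudge factor: a number, or `"auto"` for the median of the
#'   per-gene pooled standard errors of the condition.
#' @param seed RNG seed for permutation sampling.
#' @param pseudocount Added to abundances before log2 (default 1).
#' @param fcOnly If TRUE, calls gate on the fold change alone (used
#'   automatically, with a warning, when a contrast has fewer than 2
#'   replicates per group and no q-value can be computed).
#' @return Parameter list of class `DEParams`.
#' @export
deParams <- function(fcThreshold = 1.0, qMax = 0.05, nPermutations = 1000L,
                     s0 = "auto", seed = 1L, pseudocount = 1.0,
                     fcOnly = FALSE) {
  stopifnot(fcThreshold > 0, qMax > 0, qMax < 1, nPermutations >= 100)
  structure(list(fcThreshold = fcThreshold, qMax = qMax,
                 nPermutations = as.integer(nPermutations), s0 = s0,
                 seed = as.integer(seed), pseudocount = pseudocount,
                 fcOnly = isTRUE(fcOnly)),
            class = "DEParams")
}

#' RPKM normalization
#'
#' `rpkm(g, s) = counts(g, s) * 1e9 / (exon_length_g * library_size_s)`
#' (reads per kilobase of exon per million mapped reads).
#'
#' @param counts SummarizedExperiment with assay `value` in counts
#'   (from [readExpressionTable()]), or a plain counts matrix.
#' @param exonLengths Named numeric: gene -> total exon bases (> 0).
#' @return Same container with values replaced by RPKM (units metadata
#'   updated when a SummarizedExperiment is given).
#' @export
computeRpkm <- function(counts, exonLengths) {
  isSE <- is(counts, "SummarizedExperiment")
  m <- if (isSE) SummarizedExperiment::assay(counts, "value") else counts
  missing <- setdiff(rownames(m), names(exonLengths))
  if (base::length(missing)) {
    stop("exon length missing for gene(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  len <- exonLengths[rownames(m)]
  if (any(len <= 0)) stop("exon lengths must be positive")
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(m)[lib == 0], collapse = ", "))
  }
  rpkm <- sweep(m * 1e9 / len, 2, lib, "/")
  if (isSE) {
    SummarizedExperiment::assay(counts, "value") <- rpkm
    S4Vectors::metadata(counts)$units <- "rpkm"
    counts
  } else rpkm
}

#' Exon length per gene from an annotation
#'
#' Uses the longest transcript of each gene (matching the one-protein-per-
#' gene convention of the family pipeline).
#'
#' @param annot A [GenomeAnnotation-class].
#' @return Named numeric vector gene -> exon bases.
#' @export
exonLengthsFromAnnotation <- function(annot) {
  exLen <- vapply(annot@exonsByTx, function(m) sum(m[, "end"] - m[, "start"]),
                  numeric(1))
  gene <- unname(annot@txToGene[names(exLen)])
  byGene <- tapply(exLen, gene, max)
  setNames(as.numeric(byGene), names(byGene))
}

#' Tissue expression profile of family members
#'
#' Restricts an RPKM table to the family members, log2-transforms with a
#' pseudocount, and averages replicate samples per tissue on the log
#' scale. Members absent from the table get `NA` rows with a warning.
#'
#' @param rpkm SummarizedExperiment (assay `value` in RPKM) whose colData
#'   `condition` names tissues (e.g. root, stem, leaf).
#' @param memberGenes Character vector of member gene ids.
#' @param pseudocount Added before log2 (default 1).
#' @return Matrix member gene x tissue of mean log2(RPKM + pseudocount).
#' @export
tissueProfile <- function(rpkm, memberGenes, pseudocount = 1.0) {
  m <- SummarizedExperiment::assay(rpkm, "value")
  cd <- SummarizedExperiment::colData(rpkm)
  tissues <- unique(as.character(cd$condition))
  absent <- setdiff(memberGenes, rownames(m))
  if (base::length(absent)) {
    warning("member gene(s) absent from the expression table: ",
            paste(absent, collapse = ", "))
  }
  lg <- log2(m + pseudocount)
  out <- matrix(NA_real_, base::length(memberGenes), base::length(tissues),
                dimnames = list(memberGenes, tissues))
  present <- intersect(memberGenes, rownames(m))
  for (t in tissues) {
    cols <- which(cd$condition == t)
    out[present, t] <- rowMeans(lg[present, cols, drop = FALSE])
  }
  out
}

#' Filter probes by alignment quality
#'
#' A probe is retained iff it aligned with zero mismatches, hit a single
#' genomic location, that location is exonic, and it targets exactly one
#' gene. The retained set is independent of record order.
#'
#' @param probes data.frame from [readProbeTable()].
#' @return The retained subset, same columns.
#' @export
probeFilter <- function(probes) {
  ok <- !is.na(probes$gene_id) & nzchar(as.character(probes$gene_id)) &
    probes$mismatches == 0 & probes$n_genomic_hits == 1 & probes$in_exon
  # a probe listed against more than one target gene is ambiguous
  multi <- probes$probe_id[ok][duplicated(probes$probe_id[ok]) |
                                 duplicated(probes$probe_id[ok],
                                            fromLast = TRUE)]
  keep <- probes[ok & !(probes$probe_id %in% multi), , drop = FALSE]
  keep[order(keep$probe_id), , drop = FALSE]
}

#' SAM-style moderated d statistic
#'
#' `d = (mean(stress) - mean(control)) / (s + s0)` with `s` the two-sample
#' pooled standard error
#' `s = sqrt((1/n1 + 1/n2) * (ss1 + ss2) / (n1 + n2 - 2))`.
#'
#' @param stressValues,controlValues Replicate vectors (>= 2 each).
#' @param s0 Fudge factor added to the standard error.
#' @return The d statistic (scalar).
#' @export
samDStatistic <- function(stressValues, controlValues, s0 = 0) {
  n1 <- base::length(stressValues); n2 <- base::length(controlValues)
  if (n1 < 2 || n2 < 2) stop("at least 2 replicates per group are required")
  s <- pooledSe(matrix(stressValues, 1), matrix(controlValues, 1))
  if (s + s0 == 0) stop("zero variance in both groups with s0 = 0")
  (mean(stressValues) - mean(controlValues)) / (s + s0)
}

# row-wise pooled standard error for gene x replicate matrices
pooledSe <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  ss1 <- rowSums((x - rowMeans(x))^2)
  ss2 <- rowSums((y - rowMeans(y))^2)
  sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
}

# d statistics for all genes for one assignment of columns to groups
rowD <- function(mat, idx1, idx2, s0) {
  x <- mat[, idx1, drop = FALSE]; y <- mat[, idx2, drop = FALSE]
  (rowMeans(x) - rowMeans(y)) / (pooledSe(x, y) + s0)
}

#' Permutation q-values for one contrast
#'
#' Balanced label permutations of the pooled stress + control samples give
#' null d statistics. For each gene, with threshold `t = |d_g|`, the FDR
#' is the median over permutations of the null exceedance count
#' `#{|d*| >= t}` divided by the observed count `#{|d| >= t}`; the q-value
#' is the minimum of this FDR over all thresholds `t' <= |d_g|` (which
#' makes q monotone non-increasing in `|d|`), capped at 1. When the number
#' of distinct balanced splits is at most `nPermutations`, all are
#' enumerated exactly (deterministically); otherwise `nPermutations`
#' seeded random splits are drawn.
#'
#' @param mat Gene x sample matrix of log2 abundances for the pooled
#'   samples of one contrast.
#' @param isStress Logical vector over columns: TRUE for stress samples.
#' @param s0 Numeric fudge factor.
#' @param params A [deParams()] list.
#' @return list with `d` (observed statistics) and `qvalue`.
#' @export
permutationQvalues <- function(mat, isStress, s0, params = deParams()) {
  n1 <- sum(isStress); n2 <- sum(!isStress)
  if (n1 < 2 || n2 < 2) stop("at least 2 replicates per group are required")
  idx1 <- which(isStress); idx2 <- which(!isStress)
  dObs <- rowD(mat, idx1, idx2, s0)
  if (any(!is.finite(dObs))) {
    stop("non-finite d statistics (zero variance with s0 = 0?); ",
         "use a positive s0")
  }
  nTot <- n1 + n2
  nSplits <- choose(nTot, n1)
  if (nSplits <= params$nPermutations) {
    splits <- combn(nTot, n1)
  } else {
    splits <- withSeed(params$seed, {
      vapply(seq_len(params$nPermutations),
             function(i) sort(sample.int(nTot, n1)), integer(n1))
    })
  }
  absObs <- abs(dObs)
  ord <- order(absObs)                      # ascending |d|
  sortedAbs <- absObs[ord]
  G <- base::length(dObs)
  # obsCount[k] = #{|d| >= sortedAbs[k]} = G - k + 1 (with ties handled
  # via the actual ranks below)
  nullCounts <- matrix(0L, G, ncol(splits))
  for (p in seq_len(ncol(splits))) {
    g1 <- splits[, p]
    dStar <- abs(rowD(mat, g1, setdiff(seq_len(nTot), g1), s0))
    # for each observed threshold, how many null stats reach it
    nullCounts[, p] <- G - findInterval(sortedAbs, sort(dStar),
                                        left.open = TRUE)
  }
  obsCount <- G - findInterval(sortedAbs, sortedAbs, left.open = TRUE)
  fdrAtThreshold <- apply(nullCounts, 1, median) / obsCount
  fdrAtThreshold <- pmin(fdrAtThreshold, 1)
  # q = min FDR over thresholds t' <= |d_g|; the running min over
  # ascending thresholds makes q monotone non-increasing in |d|
  qSorted <- cummin(fdrAtThreshold)
  q <- numeric(G)
  q[ord] <- qSorted
  list(d = dObs, qvalue = pmin(q, 1))
}

#' Up/down/none calls from fold changes and q-values
#'
#' "up" iff `log2fc > fcThreshold` and `qvalue <= qMax`; "down"
#' symmetrically; otherwise "none". With `fcOnly = TRUE` (or `NA`
#' q-values under the fold-change-only fallback) the q gate is skipped.
#'
#' @param log2fc,qvalue Aligned matrices (or vectors).
#' @param params A [deParams()] list.
#' @return Character matrix (or vector) of calls.
#' @export
deCall <- function(log2fc, qvalue, params = deParams()) {
  qOk <- if (params$fcOnly) TRUE else (!is.na(qvalue) & qvalue <= params$qMax)
  out <- ifelse(log2fc > params$fcThreshold & qOk, "up",
                ifelse(log2fc < -params$fcThreshold & qOk, "down", "none"))
  out
}

#' Stress differential-expression analysis
#'
#' For every stress x timepoint condition in the metadata, contrasts the
#' stress replicates against the timepoint-matched controls (condition
#' `"control"`; if controls are not timepoint-resolved, all controls are
#' used): log2 fold change of means (after `log2(x + pseudocount)`),
#' SAM-style d statistic with `s0`, permutation q-values and calls.
#' Contrasts with fewer than 2 replicates in either group fall back to
#' fold-change-only calls with `NA` q-values and a warning.
#'
#' @param se SummarizedExperiment from [readExpressionTable()] with
#'   colData columns `condition` (stress names + `"control"`) and
#'   `timepoint_hours`.
#' @param params A [deParams()] list.
#' @return A [StressExpressionSet-class].
#' @export
stressDE <- function(se, params = deParams()) {
  m <- log2(SummarizedExperiment::assay(se, "value") + params$pseudocount)
  cd <- SummarizedExperiment::colData(se)
  cond <- as.character(cd$condition)
  tp <- if ("timepoint_hours" %in% colnames(cd)) {
    as.numeric(cd$timepoint_hours)
  } else rep(NA_real_, ncol(m))
  isCtl <- cond == "control"
  if (!any(isCtl)) stop("no control samples (condition == 'control')")
  stresses <- setdiff(unique(cond), "control")
  grid <- unique(data.frame(stress = cond[!isCtl], timepoint = tp[!isCtl],
                            stringsAsFactors = FALSE))
  grid <- grid[order(grid$stress, grid$timepoint), , drop = FALSE]
  G <- nrow(m); C <- nrow(grid)
  fc <- d <- q <- matrix(NA_real_, G, C)
  condNames <- sprintf("%s_%gh", grid$stress, grid$timepoint)
  colnames(fc) <- colnames(d) <- colnames(q) <- condNames
  rownames(fc) <- rownames(d) <- rownames(q) <- rownames(m)
  fellBack <- FALSE
  for (k in seq_len(C)) {
    sCols <- which(cond == grid$stress[k] &
                     (is.na(grid$timepoint[k]) | tp == grid$timepoint[k]))
    cCols <- which(isCtl & tp == grid$timepoint[k])
    if (!base::length(cCols)) cCols <- which(isCtl)
    x <- m[, sCols, drop = FALSE]; y <- m[, cCols, drop = FALSE]
    fc[, k] <- rowMeans(x) - rowMeans(y)
    if (base::length(sCols) < 2 || base::length(cCols) < 2) {
      fellBack <- TRUE
      next
    }
    s0 <- if (identical(params$s0, "auto")) {
      # floor keeps d finite on degenerate zero-variance genes
      max(median(pooledSe(x, y)), 1e-8)
    } else as.numeric(params$s0)
    sub <- cbind(x, y)
    pq <- permutationQvalues(sub, c(rep(TRUE, ncol(x)), rep(FALSE, ncol(y))),
                             s0 = s0, params = params)
    d[, k] <- pq$d
    q[, k] <- pq$qvalue
  }
  callParams <- params
  if (fellBack) {
    warning("FALLBACK fold-change-only calls: a contrast had fewer than ",
            "2 replicates per group; q-values reported as NA")
    callParams$fcOnly <- TRUE
  }
  calls <- deCall(fc, q, callParams)
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2fc = fc, d = d, qvalue = q, call = calls),
    colData = S4Vectors::DataFrame(stress = grid$stress,
                                   timepoint_hours = grid$timepoint,
                                   row.names = condNames))
  new("StressExpressionSet", out)
}
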