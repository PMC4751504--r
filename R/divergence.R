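#' Parameters for duplicate-pair divergence classification
#'
#' @param subMinPcc Minimum Pearson correlation for a
#'   subfunctionalization call (default 0.5, the published "> 0.5" rule).
#' @param neoMaxPcc Maximum correlation for a neofunctionalization call
#'   (default 0.1; the published analysis discusses negative and
#'   near-zero correlations without stating a cutoff).
#' @param minPoints Minimum pairwise-complete points (default 10).
#' @return Parameter list of class `DivergenceParams`.
#' @export
divergenceParams <- function(subMinPcc = 0.5, neoMaxPcc = 0.1,
                             minPoints = 10L) {
  stopifnot(neoMaxPcc < subMinPcc, minPoints >= 3)
  structure(list(subMinPcc = subMinPcc, neoMaxPcc = neoMaxPcc,
                 minPoints = as.integer(minPoints)),
            class = "DivergenceParams")
}

#' Pearson correlation of two expression vectors
#'
#' Standard Pearson correlation over pairwise-complete points. Returns
#' `NA` with a `reason` attribute when fewer than 3 complete points
#' remain or either vector is constant.
#'
#' @param a,b Numeric vectors of equal length (log2 fold changes over the
#'   stress x timepoint grid).
#' @return Correlation in \[-1, 1\], or NA with attribute `reason`.
#' @export
pairPcc <- function(a, b) {
  stopifnot(base::length(a) == base::length(b))
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) {
    return(structure(NA_real_, reason = "fewer than 3 complete points"))
  }
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    return(structure(NA_real_, reason = "constant vector"))
  }
  cor(a, b)
}

#' Classify expression divergence of duplicate gene pairs
#'
#' For each duplicate pair the Pearson correlation of the two genes' log2
#' fold-change profiles across the stress x timepoint grid is computed on
#' pairwise-complete points. `pcc >= subMinPcc` is called
#' subfunctionalization (duplicates retaining shared regulation),
#' `pcc <= neoMaxPcc` neofunctionalization (little or inverted
#' co-regulation), anything between is left unclassified, as are pairs
#' with fewer than `minPoints` complete points. Pairs with a gene absent
#' from the matrix are skipped with a warning.
#'
#' @param pairs data.frame with `gene_a`, `gene_b` (e.g. from
#'   [duplicationTable()]).
#' @param log2fc Gene x condition matrix of log2 fold changes.
#' @param params A [divergenceParams()] list.
#' @return data.frame: `gene_a`, `gene_b`, `pcc`, `n_points`,
#'   `classification`, `reason`.
#' @export
classifyDivergence <- function(pairs, log2fc, params = divergenceParams()) {
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (!(ga %in% rownames(log2fc)) || !(gb %in% rownames(log2fc))) {
      warning("pair ", ga, "/", gb,
              " skipped: gene absent from the fold-change matrix")
      next
    }
    va <- log2fc[ga, ]; vb <- log2fc[gb, ]
    nPts <- sum(is.finite(va) & is.finite(vb))
    pcc <- pairPcc(va, vb)
    reason <- attr(pcc, "reason")
    cls <- if (nPts < params$minPoints) {
      reason <- sprintf("only %d complete points (< %d)", nPts,
                        params$minPoints)
      "unclassified"
    } else if (is.na(pcc)) {
      "unclassified"
    } else if (pcc >= params$subMinPcc) {
      "subfunctionalization"
    } else if (pcc <= params$neoMaxPcc) {
      "neofunctionalization"
    } else {
      reason <- "intermediate correlation"
      "unclassified"
    }
    out[[base::length(out) + 1L]] <- data.frame(
      gene_a = ga, gene_b = gb, pcc = as.numeric(pcc), n_points = nPts,
      classification = cls,
      reason = if (is.null(reason)) "" else reason,
      stringsAsFactors = FALSE)
  }
  if (!base::length(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      pcc = numeric(0), n_points = integer(0),
                      classification = character(0), reason = character(0)))
  }
  do.call(rbind, out)
}

#' Classify a raw correlation value
#'
#' Threshold rule of [classifyDivergence()] applied to an
#' already-computed Pearson correlation.
#'
#' @param pcc Numeric vector of correlations.
#' @param params A [divergenceParams()] list.
#' @return Character vector of classifications.
#' @export
classifyPcc <- function(pcc, params = divergenceParams()) {
  ifelse(is.na(pcc), "unclassified",
         ifelse(pcc >= params$subMinPcc, "subfunctionalization",
                ifelse(pcc <= params$neoMaxPcc, "neofunctionalization",
                       "unclassified")))
}
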