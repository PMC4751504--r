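#' @import methods
NULL

# 20 standard amino acids plus the ambiguity code X; column order used by
# every score matrix in the package. Defined here so class validity
# methods can see it at load time.
AA_ALPHABET21 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' DomainProfile: a position-specific scoring model for one protein domain
#'
#' A log-odds (base 2) position-specific scoring matrix built from a domain
#' seed alignment, together with the Gumbel null model fitted to maximum
#' window scores of background-shuffled sequences. The null model supplies
#' E-value semantics for scan hits; a profile scores hits without being
#' calibrated, but E-values require calibration (see [calibrateNull()]).
#'
#' @slot domainName Domain label, e.g. `"AP2"` or `"B3"`.
#' @slot scores Numeric matrix, L x 21 (20 amino acids plus X), log-odds in
#'   bits; the X column is identically zero.
#' @slot consensus Length-L character string, the most frequent residue per
#'   match column (ties broken alphabetically).
#' @slot background Numeric length-21 frequency vector summing to one.
#' @slot nullMu,nullBeta Gumbel location and scale of the calibrated null
#'   (NA before calibration).
#' @slot nullScores Maximum window scores of the shuffled sequences used for
#'   calibration (empty before calibration).
#' @slot calibrationN Number of shuffles used (0 before calibration).
#' @export
setClass("DomainProfile",
  representation(
    domainName   = "character",
    scores       = "matrix",
    consensus    = "character",
    background   = "numeric",
    nullMu       = "numeric",
    nullBeta     = "numeric",
    nullScores   = "numeric",
    calibrationN = "integer"
  ),
  prototype(
    nullMu = NA_real_, nullBeta = NA_real_,
    nullScores = numeric(0), calibrationN = 0L
  )
)

setValidity("DomainProfile", function(object) {
  msg <- character(0)
  sc <- object@scores
  if (!is.numeric(sc) || ncol(sc) != 21L)
    msg <- c(msg, "scores must be a numeric L x 21 matrix")
  if (!identical(colnames(sc), AA_ALPHABET21))
    msg <- c(msg, "scores columns must be the 20 amino acids plus X, in order")
  if (nrow(sc) < 10L)
    msg <- c(msg, "profile length L must be >= 10")
  if (any(sc[, "X"] != 0))
    msg <- c(msg, "the X column of scores must be identically zero")
  if (abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background frequencies must sum to 1")
  if (nchar(object@consensus) != nrow(sc))
    msg <- c(msg, "consensus length must equal profile length")
  if (!is.na(object@nullBeta) && object@nullBeta <= 0)
    msg <- c(msg, "Gumbel scale beta must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn DomainProfile Number of match columns L.
#' @param x,object A `DomainProfile`.
#' @export
setMethod("length", "DomainProfile", function(x) nrow(x@scores))

#' @describeIn DomainProfile Whether a Gumbel null has been fitted.
#' @export
setGeneric("isCalibrated", function(object) standardGeneric("isCalibrated"))

#' @rdname DomainProfile
#' @export
setMethod("isCalibrated", "DomainProfile", function(object) {
  is.finite(object@nullMu) && is.finite(object@nullBeta)
})

#' @describeIn DomainProfile Domain name accessor.
#' @export
setGeneric("domainName", function(object) standardGeneric("domainName"))

#' @rdname DomainProfile
#' @export
setMethod("domainName", "DomainProfile", function(object) object@domainName)

#' @describeIn DomainProfile Consensus sequence accessor.
#' @export
setGeneric("profileConsensus", function(object) standardGeneric("profileConsensus"))

#' @rdname DomainProfile
#' @export
setMethod("profileConsensus", "DomainProfile", function(object) object@consensus)

setMethod("show", "DomainProfile", function(object) {
  cat("DomainProfile '", object@domainName, "': L = ", length(object),
      ", consensus ", substr(object@consensus, 1, 24),
      if (length(object) > 24) "..." else "", "\n", sep = "")
  if (isCalibrated(object)) {
    cat(sprintf("  null: Gumbel(mu = %.3f, beta = %.3f) from %d shuffles\n",
                object@nullMu, object@nullBeta, object@calibrationN))
  } else {
    cat("  null: uncalibrated (E-values unavailable)\n")
  }
})

#' AnchoredMSA: a profile-anchored multiple alignment of domain regions
#'
#' Each row is a domain subsequence projected onto the L match columns of a
#' [DomainProfile-class] by global alignment to the profile consensus;
#' insertions relative to the consensus are discarded and deletions become
#' gaps, so column homology is inherited from the profile.
#'
#' @slot ids Sequence identifiers (unique).
#' @slot rows Character vector of residue-or-gap strings, all of width L.
#' @slot profileName Name of the anchoring profile.
#' @export
setClass("AnchoredMSA",
  representation(ids = "character", rows = "character",
                 profileName = "character"))

setValidity("AnchoredMSA", function(object) {
  msg <- character(0)
  if (length(object@ids) != length(object@rows))
    msg <- c(msg, "ids and rows must have equal length")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "ids must be unique")
  w <- unique(nchar(object@rows))
  if (length(w) > 1)
    msg <- c(msg, "all rows must have equal width")
  if (length(object@rows) &&
      any(!grepl("[^-]", object@rows)))
    msg <- c(msg, "every row must contain at least one non-gap residue")
  if (length(msg)) msg else TRUE
})

#' @describeIn AnchoredMSA Number of rows (sequences).
#' @param x A `AnchoredMSA`.
#' @export
setMethod("length", "AnchoredMSA", function(x) length(x@ids))

setMethod("show", "AnchoredMSA", function(object) {
  cat("AnchoredMSA: ", length(object), " sequences x ",
      if (length(object)) nchar(object@rows[1]) else 0L,
      " columns (profile '", object@profileName, "')\n", sep = "")
})

#' Convert an AnchoredMSA to a character matrix
#'
#' @param msa An [AnchoredMSA-class].
#' @return Character matrix, rows named by sequence id, one column per
#'   profile match column; gaps are `"-"`.
#' @export
msaMatrix <- function(msa) {
  stopifnot(is(msa, "AnchoredMSA"))
  if (!length(msa)) return(matrix(character(0), 0, 0))
  m <- do.call(rbind, strsplit(msa@rows, ""))
  rownames(m) <- msa@ids
  m
}

#' GenomeAnnotation: gene models parsed from GFF3
#'
#' Gene, transcript and exon structure with internal 0-based half-open
#' coordinates (GFF3's 1-based inclusive intervals are converted at the I/O
#' boundary). Transcript identifiers double as protein identifiers, which is
#' how the pipeline joins proteome FASTA entries to gene loci.
#'
#' @slot genes A `GRanges` of gene spans with a `gene_id` metadata column
#'   (ranges kept 1-based inside GRanges; use [geneTable()] for the 0-based
#'   view).
#' @slot exonsByTx Named list: transcript id -> integer matrix with columns
#'   `start`, `end` (0-based half-open, sorted, non-overlapping).
#' @slot txToGene Named character: transcript id -> gene id.
#' @export
setClass("GenomeAnnotation",
  representation(genes = "GRanges", exonsByTx = "list",
                 txToGene = "character"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character(0)
  if (is.null(object@genes$gene_id))
    msg <- c(msg, "genes must carry a gene_id metadata column")
  if (!all(names(object@exonsByTx) %in% names(object@txToGene)))
    msg <- c(msg, "every transcript with exons must map to a gene")
  for (tx in names(object@exonsByTx)) {
    ex <- object@exonsByTx[[tx]]
    if (any(ex[, "end"] <= ex[, "start"])) {
      msg <- c(msg, sprintf("transcript %s has an empty or inverted exon", tx))
      break
    }
    if (nrow(ex) > 1 && (any(diff(ex[, "start"]) <= 0) ||
                         any(ex[-1, "start"] < ex[-nrow(ex), "end"]))) {
      msg <- c(msg, sprintf("exons of transcript %s overlap or are unsorted", tx))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation: ", length(object@genes), " genes, ",
      length(object@exonsByTx), " transcripts on ",
      length(unique(as.character(GenomicRanges::seqnames(object@genes)))),
      " chromosomes\n", sep = "")
})

#' StressExpressionSet: per-condition differential-expression results
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose columns are stress x
#' timepoint contrasts against matched controls and whose assays are the
#' log2 fold change (`log2fc`), the SAM-style moderated statistic (`d`), the
#' permutation q-value (`qvalue`), and the up/down/none call (`call`).
#'
#' At the default thresholds a call is "up" iff `log2fc` exceeds the
#' fold-change threshold and `qvalue` is at most the q cutoff, and
#' symmetrically for "down".
#'
#' @export
setClass("StressExpressionSet", contains = "SummarizedExperiment")

setValidity("StressExpressionSet", function(object) {
  msg <- character(0)
  need <- c("log2fc", "d", "qvalue", "call")
  have <- SummarizedExperiment::assayNames(object)
  if (!all(need %in% have))
    msg <- c(msg, paste("missing assays:",
                        paste(setdiff(need, have), collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("stress", "timepoint_hours") %in% colnames(cd)))
    msg <- c(msg, "colData must contain stress and timepoint_hours")
  if ("qvalue" %in% have) {
    q <- SummarizedExperiment::assay(object, "qvalue")
    if (any(q < 0 | q > 1, na.rm = TRUE))
      msg <- c(msg, "q-values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
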