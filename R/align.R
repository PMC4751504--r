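#' Pairwise global and local protein alignment with similarity metrics
#'
#' Needleman-Wunsch (`globalAlign`) and Smith-Waterman (`localAlign`) with
#' affine gaps (a length-k gap costs `gapOpen + k * gapExtend`), delegated
#' to [Biostrings::pairwiseAlignment()]. On top of the optimal alignment
#' the functions compute the metrics the duplication criteria threshold:
#' \describe{
#'   \item{identity}{identical aligned residue pairs / aligned residue pairs}
#'   \item{similarity}{aligned pairs with a positive substitution score /
#'     aligned residue pairs (classic percent-similar)}
#'   \item{coverage}{aligned residue pairs / length of the longer input
#'     sequence ("sequence matching length")}
#' }
#' Aligned residue pairs are columns where both sequences have a residue
#' (gap columns are excluded from all numerators and denominators except
#' coverage's fixed denominator).
#'
#' @param a,b Protein sequences (single character strings).
#' @param matrixName Substitution matrix name (default `"BLOSUM62"`; any
#'   matrix shipped with \pkg{Biostrings}).
#' @param gapOpen,gapExtend Affine gap parameters (defaults 10 and 0.5).
#' @return A list with `score`, `alignedA`, `alignedB` (gapped strings of
#'   equal width) and `metrics` (one-row data.frame: `identity`,
#'   `similarity`, `coverage`, `score`).
#' @export
globalAlign <- function(a, b, matrixName = "BLOSUM62",
                        gapOpen = 10, gapExtend = 0.5) {
  alignPair(a, b, matrixName, gapOpen, gapExtend, type = "global")
}

#' @rdname globalAlign
#' @export
localAlign <- function(a, b, matrixName = "BLOSUM62",
                       gapOpen = 10, gapExtend = 0.5) {
  alignPair(a, b, matrixName, gapOpen, gapExtend, type = "local")
}

substitutionMatrix <- local({
  cache <- list()
  function(matrixName) {
    if (!is.null(cache[[matrixName]])) return(cache[[matrixName]])
    ok <- tryCatch({
      e <- new.env()
      utils::data(list = matrixName, package = "Biostrings", envir = e)
      get(matrixName, envir = e)
    }, warning = function(w) NULL, error = function(e) NULL)
    if (is.null(ok)) stop("unknown substitution matrix: ", matrixName)
    cache[[matrixName]] <<- ok
    ok
  }
})

alignPair <- function(a, b, matrixName, gapOpen, gapExtend, type) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  sm <- substitutionMatrix(matrixName)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sm, gapOpening = gapOpen, gapExtension = gapExtend,
    type = type)
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  metrics <- alignMetrics(ga, gb, sm, longer = max(nchar(a), nchar(b)),
                          score = Biostrings::score(pa))
  list(score = Biostrings::score(pa), alignedA = ga, alignedB = gb,
       metrics = metrics)
}

# identity / similarity / coverage from a pair of gapped strings
alignMetrics <- function(ga, gb, sm, longer, score) {
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  both <- ca != "-" & cb != "-"
  np <- sum(both)
  if (np == 0) {
    return(data.frame(identity = 0, similarity = 0, coverage = 0,
                      score = score))
  }
  ra <- ca[both]; rb <- cb[both]
  ident <- sum(ra == rb) / np
  subsc <- sm[cbind(ra, rb)]
  simil <- sum(subsc > 0) / np
  data.frame(identity = ident, similarity = simil,
             coverage = np / longer, score = score)
}

#' Alignment metrics for one sequence against many
#'
#' Vectorized convenience used by the similarity-search candidate route and
#' the duplication scans: aligns `query` against every element of
#' `subjects` and returns the metric table.
#'
#' @param query Single sequence (character).
#' @param subjects Named character vector or `AAStringSet`.
#' @param type `"global"` or `"local"`.
#' @param computeSimilarity Also compute the positive-substitution
#'   similarity fraction (slower: requires materializing every gapped
#'   alignment); when FALSE that column is `NA`.
#' @inheritParams globalAlign
#' @return data.frame with one row per subject: `subject_id`, `identity`,
#'   `similarity`, `coverage`, `score`.
#' @export
alignToSet <- function(query, subjects, type = c("local", "global"),
                       matrixName = "BLOSUM62", gapOpen = 10, gapExtend = 0.5,
                       computeSimilarity = FALSE) {
  type <- match.arg(type)
  if (is(subjects, "AAStringSet")) {
    ids <- names(subjects); subjects <- as.character(subjects)
  } else ids <- names(subjects)
  if (is.null(ids)) ids <- as.character(seq_along(subjects))
  sm <- substitutionMatrix(matrixName)
  # one C call: all subjects as patterns against the single query
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects), Biostrings::AAString(query),
    substitutionMatrix = sm, gapOpening = gapOpen, gapExtension = gapExtend,
    type = type)
  np <- Biostrings::nmatch(pa) + Biostrings::nmismatch(pa)
  longer <- pmax(nchar(query), nchar(subjects))
  identity <- ifelse(np > 0, Biostrings::nmatch(pa) / np, 0)
  coverage <- np / longer
  sc <- Biostrings::score(pa)
  similarity <- rep(NA_real_, length(subjects))
  if (computeSimilarity) {
    ga <- as.character(Biostrings::alignedPattern(pa))
    gb <- as.character(Biostrings::alignedSubject(pa))
    similarity <- vapply(seq_along(subjects), function(i) {
      alignMetrics(ga[i], gb[i], sm, longer = longer[i],
                   score = sc[i])$similarity
    }, numeric(1))
  }
  data.frame(subject_id = ids, identity = identity, similarity = similarity,
             coverage = coverage, score = sc, stringsAsFactors = FALSE)
}
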