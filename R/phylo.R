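#' Project domain subsequences onto profile match columns
#'
#' Globally aligns each domain subsequence to the profile consensus
#' (BLOSUM62, gap open 10 / extend 0.5) and maps its residues onto the L
#' consensus columns: insertions relative to the consensus are discarded
#' and deletions become gaps. Column homology is therefore inherited from
#' the profile, making the alignment deterministic. Rows occupying fewer
#' than `minOccupied` of the columns are dropped with a warning.
#'
#' @param profile A [DomainProfile-class].
#' @param domainSeqs Named character vector (or `AAStringSet`) of domain
#'   subsequences, typically cut from proteins at [scanSequence()] hit
#'   coordinates.
#' @param minOccupied Minimum fraction of non-gap columns per row
#'   (default 0.3).
#' @return An [AnchoredMSA-class].
#' @export
anchorMSA <- function(profile, domainSeqs, minOccupied = 0.3) {
  stopifnot(is(profile, "DomainProfile"))
  if (is(domainSeqs, "AAStringSet")) {
    domainSeqs <- setNames(as.character(domainSeqs), names(domainSeqs))
  }
  stopifnot(!is.null(names(domainSeqs)))
  cons <- profileConsensus(profile)
  L <- base::length(profile)
  rows <- character(0); ids <- character(0)
  for (i in seq_along(domainSeqs)) {
    al <- globalAlign(cons, domainSeqs[[i]])
    ca <- strsplit(al$alignedA, "")[[1]]   # consensus, gapped
    cb <- strsplit(al$alignedB, "")[[1]]   # subsequence, gapped
    inCons <- ca != "-"                    # skip insertions
    row <- cb[inCons]
    row[row == "-"] <- "-"
    rowStr <- paste(row, collapse = "")
    if (sum(row != "-") < minOccupied * L) {
      warning("dropping ", names(domainSeqs)[i],
              ": aligns with fewer than ", round(100 * minOccupied),
              "% of profile columns")
      next
    }
    rows <- c(rows, rowStr); ids <- c(ids, names(domainSeqs)[i])
  }
  new("AnchoredMSA", ids = ids, rows = rows,
      profileName = domainName(profile))
}

#' Pairwise distances from an anchored alignment
#'
#' p-distance (mismatches / compared sites) with pairwise deletion: only
#' columns where both rows carry a residue are compared. The
#' Poisson-corrected variant applies `d = -ln(1 - p)`. A pair sharing zero
#' non-gap columns is an error.
#'
#' @param msa An [AnchoredMSA-class] with at least 3 rows.
#' @param model `"p"` (default) or `"poisson"`.
#' @return list of class `DistanceMatrix`: `ids`, `d` (symmetric matrix
#'   with zero diagonal).
#' @export
pDistance <- function(msa, model = c("p", "poisson")) {
  model <- match.arg(model)
  stopifnot(is(msa, "AnchoredMSA"))
  n <- base::length(msa)
  if (n < 3) stop("at least 3 sequences are required")
  m <- msaMatrix(msa)
  # one-hot matrix products give all pairwise match/site counts at once
  nonGap <- (m != "-") * 1L
  shared <- nonGap %*% t(nonGap)
  matches <- matrix(0, n, n)
  for (a in unique(as.vector(m))) {
    if (a == "-") next
    ia <- (m == a) * 1L
    matches <- matches + ia %*% t(ia)
  }
  zero <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)
  if (nrow(zero)) {
    stop("no shared non-gap columns between ", msa@ids[zero[1, 1]],
         " and ", msa@ids[zero[1, 2]])
  }
  p <- (shared - matches) / shared
  diag(p) <- 0
  d <- if (model == "poisson") {
    if (any(p[upper.tri(p)] >= 1))
      stop("Poisson correction undefined for p-distance of 1")
    -log(1 - p)
  } else p
  dimnames(d) <- list(msa@ids, msa@ids)
  structure(list(ids = msa@ids, d = d), class = "DistanceMatrix")
}

#' Construct a distance matrix object
#'
#' @param d Symmetric numeric matrix with zero diagonal; dimnames supply
#'   ids unless given.
#' @param ids Optional ids.
#' @return A `DistanceMatrix`.
#' @export
distanceMatrix <- function(d, ids = rownames(d)) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d), class = "DistanceMatrix")
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei agglomeration: at each step join the pair (i, j)
#' minimizing `Q(i,j) = (n-2) d(i,j) - r_i - r_j` (ties broken by the
#' smallest index pair in the current cluster order), with the standard
#' branch-length and distance-update formulas. Negative branch lengths are
#' clamped to zero in the returned tree; the raw values are retained in
#' `attr(tree, "rawTree")`. The result is unrooted with a trifurcating
#' root node.
#'
#' @param dm A `DistanceMatrix` (from [pDistance()] or [distanceMatrix()]).
#' @return An [ape::phylo] tree.
#' @export
njTree <- function(dm) {
  if (!inherits(dm, "DistanceMatrix")) dm <- distanceMatrix(dm)
  d <- dm$d
  n <- nrow(d)
  if (n < 3) stop("neighbor joining requires at least 3 taxa")
  # each active cluster holds a pair of Newick fragments (clamped, raw)
  lab <- dm$ids
  nwk <- lab
  raw <- lab
  fmt <- function(x) sprintf("%.10g", x)
  while (n > 3) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    mn <- min(Q)
    cand <- which(Q == mn & upper.tri(Q), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    newNwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(max(bi, 0)),
                      nwk[j], fmt(max(bj, 0)))
    newRaw <- sprintf("(%s:%s,%s:%s)", raw[i], fmt(bi), raw[j], fmt(bj))
    dNew <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    nwk <- c(nwk[keep], newNwk)
    raw <- c(raw[keep], newRaw)
    n <- n - 1
  }
  bA <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  bB <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  bC <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  tre <- ape::read.tree(text = sprintf("(%s:%s,%s:%s,%s:%s);",
    nwk[1], fmt(max(bA, 0)), nwk[2], fmt(max(bB, 0)), nwk[3], fmt(max(bC, 0))))
  rawT <- ape::read.tree(text = sprintf("(%s:%s,%s:%s,%s:%s);",
    raw[1], fmt(bA), raw[2], fmt(bB), raw[3], fmt(bC)))
  attr(tre, "rawTree") <- rawT
  tre
}

# canonical bipartition keys for every internal (non-root) node of a tree;
# a key is the sorted tip-label set of the side NOT containing the
# reference label (the alphabetically smallest tip of refLabels)
bipartitionKeys <- function(tree, refLabels = tree$tip.label) {
  ref <- min(refLabels)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  all <- sort(labs)
  keys <- vapply(seq_along(pp), function(k) {
    side <- sort(labs[pp[[k]]])
    if (ref %in% side) side <- setdiff(all, side)
    paste(side, collapse = ";")
  }, character(1))
  # first entry is the root (all tips -> empty complement); drop it
  keys[-1]
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement B times, rebuilds the NJ
#' tree for each replicate, and annotates every internal edge of the
#' full-data tree with the number of replicates containing the same leaf
#' bipartition. Supports are stored as integer counts in `node.label`
#' (the trifurcating root gets `NA`) with `attr(tree, "B")` recording the
#' replicate count; display as percentages is left to the caller.
#'
#' @param msa An [AnchoredMSA-class].
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed RNG seed (default 1).
#' @param model Distance model passed to [pDistance()].
#' @return The full-data [ape::phylo] with `node.label` supports.
#' @export
bootstrapSupport <- function(msa, B = 1000L, seed = 1L, model = "p") {
  stopifnot(is(msa, "AnchoredMSA"), B >= 1)
  # canonicalize row order so supports depend only on the MSA content,
  # not on the order sequences were supplied (NJ tie-breaking is
  # index-based, so row order could otherwise leak into tied joins)
  ord <- order(msa@ids)
  msa <- new("AnchoredMSA", ids = msa@ids[ord], rows = msa@rows[ord],
             profileName = msa@profileName)
  m <- msaMatrix(msa)
  L <- ncol(m)
  full <- njTree(pDistance(msa, model = model))
  keys <- bipartitionKeys(full)
  counts <- setNames(integer(base::length(keys)), keys)
  withSeed(seed, {
    for (b in seq_len(B)) {
      cols <- sample.int(L, L, replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      rowsB <- apply(mb, 1, paste, collapse = "")
      msaB <- new("AnchoredMSA", ids = msa@ids, rows = unname(rowsB),
                  profileName = msa@profileName)
      tb <- tryCatch(njTree(pDistance(msaB, model = model)),
                     error = function(e) NULL)
      if (is.null(tb)) next
      kb <- unique(bipartitionKeys(tb, refLabels = full$tip.label))
      hit <- keys %in% kb
      counts[hit] <- counts[hit] + 1L
    }
  })
  full$node.label <- c(NA_integer_, unname(counts))
  attr(full, "B") <- as.integer(B)
  full
}

#' Label tree leaves from anchored reference groups
#'
#' For each query leaf the smallest bipartition side (over all tree edges)
#' that contains the leaf and at least one anchor is found; if every
#' anchor in that side carries the same group label the query inherits it,
#' otherwise the query stays `"unclassified"` (groups are never forced).
#' An anchor leaf trivially receives its own label.
#'
#' @param tree An [ape::phylo].
#' @param anchors Named character vector: anchor leaf label -> group label
#'   (e.g. `"DREB"`, `"ERF"`, `"A1"`).
#' @return Named character vector over all leaves: group label or
#'   `"unclassified"`.
#' @export
labelGroups <- function(tree, anchors) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  anchorIds <- intersect(names(anchors), tips)
  if (!base::length(anchorIds)) stop("no anchor leaves present in the tree")
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sides <- list()
  # internal edges: clade and complement; pendant edges: singleton sides
  for (k in seq_along(pp)[-1]) {
    clade <- labs[pp[[k]]]
    sides[[base::length(sides) + 1L]] <- clade
    sides[[base::length(sides) + 1L]] <- setdiff(tips, clade)
  }
  for (t in tips) {
    sides[[base::length(sides) + 1L]] <- t
    sides[[base::length(sides) + 1L]] <- setdiff(tips, t)
  }
  sides[[base::length(sides) + 1L]] <- tips  # fallback: whole tree
  sizes <- vapply(sides, base::length, integer(1))
  ord <- order(sizes, vapply(sides, function(s) paste(sort(s), collapse = ";"),
                             character(1)))
  sides <- sides[ord]
  hasAnchor <- vapply(sides, function(s) any(s %in% anchorIds), logical(1))
  out <- setNames(rep("unclassified", base::length(tips)), tips)
  for (q in tips) {
    for (k in which(hasAnchor)) {
      if (q %in% sides[[k]]) {
        inside <- unique(anchors[intersect(sides[[k]], anchorIds)])
        if (base::length(inside) == 1L) out[[q]] <- inside
        break
      }
    }
  }
  out
}
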