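#' Build a position-specific scoring model from a domain seed alignment
#'
#' Columns with at least 50% gaps are dropped; the remaining match columns
#' yield per-residue log-odds scores
#' \deqn{s_{i,a} = \log_2 \frac{(c_{i,a} + 0.1) / (n_i + 2.1)}{b_a}}
#' where \eqn{c_{i,a}} counts residue \eqn{a} in match column \eqn{i},
#' \eqn{n_i} is the number of residues in that column, and the background
#' \eqn{b_a} is the overall residue frequency of the seed under the same
#' add-0.1 pseudocounting (0.1 per each of the 21 symbols, hence the 2.1).
#' The X column is fixed at zero so unknown residues are score-neutral.
#' The consensus takes the most frequent residue per column, ties broken
#' alphabetically.
#'
#' @param seed A gapped [Biostrings::AAStringSet] (all sequences equal
#'   width; at least 5 sequences), e.g. from
#'   `readProteinFasta(path, gapped = TRUE)`.
#' @param domainName Label for the domain, e.g. `"AP2"`.
#' @param gapMax Maximum gap fraction for a column to count as a match
#'   column (default 0.5).
#' @param pseudocount Additive pseudocount (default 0.1).
#' @return An uncalibrated [DomainProfile-class].
#' @export
buildProfile <- function(seed, domainName, gapMax = 0.5, pseudocount = 0.1) {
  if (is.character(seed)) seed <- Biostrings::AAStringSet(seed)
  n <- length(seed)
  if (n < 5) stop("seed alignment must contain at least 5 sequences, got ", n)
  widths <- Biostrings::width(seed)
  if (length(unique(widths)) != 1) {
    stop("ragged seed alignment: sequence widths ",
         paste(unique(widths), collapse = ", "))
  }
  m <- do.call(rbind, strsplit(as.character(seed), ""))
  isGap <- m == "-"
  gapFrac <- colMeans(isGap)
  keep <- which(gapFrac < gapMax)
  if (length(keep) < 10)
    stop("fewer than 10 match columns after dropping gappy columns")
  aas20 <- AA_ALPHABET21[1:20]

  # background from the whole seed (all columns), same pseudocounting
  res <- m[!isGap]
  bgCounts <- table(factor(res, levels = AA_ALPHABET21))
  background <- (as.numeric(bgCounts) + pseudocount) /
    (length(res) + 21 * pseudocount)
  names(background) <- AA_ALPHABET21

  L <- length(keep)
  scores <- matrix(0, L, 21, dimnames = list(NULL, AA_ALPHABET21))
  consensus <- character(L)
  for (j in seq_len(L)) {
    col <- m[, keep[j]]
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = AA_ALPHABET21))
    p <- (as.numeric(cnt) + pseudocount) / (length(col) + 21 * pseudocount)
    s <- log2(p / background)
    s[21] <- 0  # X is score-neutral
    scores[j, ] <- s
    cnt20 <- cnt[aas20]
    consensus[j] <- aas20[which.max(cnt20)]  # which.max: first = alphabetical tie-break
  }
  new("DomainProfile", domainName = domainName, scores = scores,
      consensus = paste(consensus, collapse = ""), background = background)
}

# Scores of all admissible profile placements on an integer-encoded
# sequence. Placements are offsets o in [-(L-1), n-1]: profile column j
# covers sequence position o + j. Overlap with the sequence must be at
# least min(n, ceiling(L/2)): full-width windows plus end-truncated windows
# that still cover half the profile (or the whole sequence when the
# sequence itself is shorter). Returns a data.frame of placements.
profilePlacements <- function(profile, seqInt) {
  L <- length(profile)
  n <- length(seqInt)
  if (n == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0), truncated = logical(0)))
  }
  minOv <- min(n, ceiling(L / 2))
  sc <- profile@scores
  # M[j, i] = score of profile column j against residue at position i
  M <- matrix(sc[cbind(rep(seq_len(L), n), rep(seqInt, each = L))], L, n)
  offsets <- seq(-(L - 1L), n - 1L)
  starts <- pmax(offsets + 1L, 1L)          # first covered seq position
  ends <- pmin(offsets + L, n)              # last covered seq position
  ov <- ends - starts + 1L
  keep <- ov >= minOv
  offsets <- offsets[keep]; starts <- starts[keep]; ends <- ends[keep]
  full <- (ends - starts + 1L) == L
  score <- numeric(length(offsets))
  if (any(full)) {
    # vectorized shift-and-add over the L profile columns
    W <- numeric(n - L + 1L)
    for (j in seq_len(L)) W <- W + M[j, j:(n - L + j)]
    score[full] <- W[offsets[full] + 1L]
  }
  for (k in which(!full)) {
    jj <- (starts[k] - offsets[k]):(ends[k] - offsets[k])
    score[k] <- sum(M[cbind(jj, starts[k]:ends[k])])
  }
  data.frame(start = starts - 1L,  # 0-based half-open on the protein
             end = ends,
             score = score,
             truncated = (ends - starts + 1L) < L)
}

encodeSeq <- function(x) {
  v <- match(strsplit(x, "")[[1]], AA_ALPHABET21)
  if (anyNA(v)) stop("sequence contains residues outside the 21-letter alphabet")
  v
}

#' Scan a protein for domain hits
#'
#' Slides the profile gaplessly across the protein (placements hanging off
#' either end are allowed while they still cover at least half the profile,
#' and are flagged `truncated`). A placement's score is the sum of its
#' column log-odds. Candidate placements with positive score are accepted
#' greedily best-score-first, discarding any placement that overlaps an
#' accepted one by more than L/2 residues. E-values come from the
#' calibrated Gumbel null: `E = D * (1 - exp(-exp(-(s - mu)/beta)))`.
#'
#' @param profile A calibrated [DomainProfile-class] (scanning without
#'   calibration is allowed but yields `NA` E-values).
#' @param seq A single protein sequence (character or `AAStringSet` of 1).
#' @param proteinId Identifier recorded in the hits.
#' @param D Database size for the E-value (number of proteins scanned in
#'   the run; default 1).
#' @return data.frame of hits: `protein_id`, `domain`, `start`, `end`
#'   (0-based half-open), `score` (bits), `evalue`, `truncated`, sorted by
#'   decreasing score.
#' @export
scanSequence <- function(profile, seq, proteinId = "query", D = 1) {
  stopifnot(is(profile, "DomainProfile"))
  if (is(seq, "AAStringSet")) {
    if (is.null(proteinId) && !is.null(names(seq))) proteinId <- names(seq)[1]
    seq <- as.character(seq)[1]
  }
  empty <- data.frame(protein_id = character(0), domain = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), evalue = numeric(0),
                      truncated = logical(0))
  if (!nzchar(seq)) return(empty)
  pl <- profilePlacements(profile, encodeSeq(seq))
  pl <- pl[pl$score > 0, , drop = FALSE]
  if (!nrow(pl)) return(empty)
  pl <- pl[order(-pl$score, pl$start), , drop = FALSE]
  L <- length(profile)
  accepted <- integer(0)
  for (k in seq_len(nrow(pl))) {
    if (length(accepted)) {
      ovl <- pmin(pl$end[accepted], pl$end[k]) -
        pmax(pl$start[accepted], pl$start[k])
      if (any(ovl > L / 2)) next
    }
    accepted <- c(accepted, k)
  }
  pl <- pl[accepted, , drop = FALSE]
  ev <- if (isCalibrated(profile)) {
    evalueFromScore(profile, pl$score, D = D)
  } else NA_real_
  data.frame(protein_id = proteinId, domain = profile@domainName,
             start = pl$start, end = pl$end, score = pl$score,
             evalue = ev, truncated = pl$truncated,
             row.names = NULL)
}

#' E-value of a score under a calibrated profile null
#'
#' @param profile Calibrated [DomainProfile-class].
#' @param score Numeric vector of bit scores.
#' @param D Database size (number of sequences searched).
#' @return Expected count of hits scoring at least `score` in a database of
#'   `D` sequences: `D * (1 - exp(-exp(-(score - mu)/beta)))`.
#' @export
evalueFromScore <- function(profile, score, D = 1) {
  if (!isCalibrated(profile)) stop("profile is not calibrated")
  D * (1 - exp(-exp(-(score - profile@nullMu) / profile@nullBeta)))
}

#' Calibrate a profile's null score distribution by shuffling
#'
#' Draws `nShuffles` i.i.d. sequences of the given length from the
#' profile's background residue distribution, records each sequence's
#' maximum placement score (same placement rules as [scanSequence()]), and
#' fits a Gumbel distribution by the method of moments:
#' `beta = sd * sqrt(6)/pi`, `mu = mean - gamma * beta` (Euler-Mascheroni
#' gamma). Deterministic for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param profile A [DomainProfile-class].
#' @param nShuffles Number of null sequences (>= 200; smaller fits are too
#'   unstable to trust).
#' @param length Null sequence length (defaults to 2x profile length; in
#'   pipeline use, the mean scanned-protein length).
#' @param seed RNG seed.
#' @return The profile with `nullMu`, `nullBeta`, `nullScores`,
#'   `calibrationN` filled in.
#' @export
calibrateNull <- function(profile, nShuffles = 500L, length = 2L * base::length(profile),
                          seed = 1L) {
  stopifnot(is(profile, "DomainProfile"))
  if (nShuffles < 200) {
    stop("nShuffles must be >= 200 (got ", nShuffles,
         "); smaller null samples give unstable Gumbel fits")
  }
  bg <- profile@background
  maxScores <- withSeed(seed, {
    vapply(seq_len(nShuffles), function(i) {
      s <- sample.int(21L, size = length, replace = TRUE, prob = bg)
      max(profilePlacements(profile, s)$score)
    }, numeric(1))
  })
  beta <- sd(maxScores) * sqrt(6) / pi
  if (!is.finite(beta) || beta <= 0) stop("degenerate null score spread")
  gamma <- 0.57721566490153286
  mu <- mean(maxScores) - gamma * beta
  profile@nullMu <- mu
  profile@nullBeta <- beta
  profile@nullScores <- maxScores
  profile@calibrationN <- as.integer(nShuffles)
  validObject(profile)
  profile
}

#' Scan a whole proteome with one or more profiles
#'
#' @param profiles A [DomainProfile-class] or list of them.
#' @param proteome Named [Biostrings::AAStringSet].
#' @param D Database size for E-values; defaults to `length(proteome)`.
#' @return Combined hits data.frame (see [scanSequence()]).
#' @export
scanProteome <- function(profiles, proteome, D = base::length(proteome)) {
  if (is(profiles, "DomainProfile")) profiles <- list(profiles)
  ids <- names(proteome)
  seqs <- as.character(proteome)
  out <- vector("list", length(profiles) * length(ids))
  k <- 0L
  for (pf in profiles) {
    for (i in seq_along(ids)) {
      k <- k + 1L
      out[[k]] <- scanSequence(pf, seqs[i], proteinId = ids[i], D = D)
    }
  }
  do.call(rbind, out)
}

#' Serialize a profile to a versioned TSV
#'
#' Header comment lines carry the format version, domain name, consensus,
#' Gumbel parameters and background; the body is the L x 21 score matrix.
#'
#' @param profile A [DomainProfile-class].
#' @param path Output path.
#' @return `path` invisibly; `readProfileTsv` returns the profile.
#' @export
writeProfileTsv <- function(profile, path) {
  stopifnot(is(profile, "DomainProfile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# ap2erf-profile-tsv v1",
    paste0("# domain=", profile@domainName),
    paste0("# consensus=", profile@consensus),
    paste0("# mu=", format(profile@nullMu, digits = 17)),
    paste0("# beta=", format(profile@nullBeta, digits = 17)),
    paste0("# calibration_n=", profile@calibrationN),
    paste0("# background=", paste(format(profile@background, digits = 17),
                                  collapse = ","))
  ), con)
  writeLines(paste(c("column", AA_ALPHABET21), collapse = "\t"), con)
  for (j in seq_len(nrow(profile@scores))) {
    writeLines(paste(c(j, format(profile@scores[j, ], digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeProfileTsv
#' @export
readProfileTsv <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# ap2erf-profile-tsv"))
    stop("not an ap2erf profile TSV: ", path)
  hdr <- function(key) {
    ln <- grep(paste0("^# ", key, "="), lines, value = TRUE)[1]
    sub(paste0("^# ", key, "="), "", ln)
  }
  body <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t")
  scores <- as.matrix(body[, -1])
  colnames(scores) <- AA_ALPHABET21
  rownames(scores) <- NULL
  bg <- as.numeric(strsplit(hdr("background"), ",")[[1]])
  names(bg) <- AA_ALPHABET21
  new("DomainProfile",
      domainName = hdr("domain"), scores = scores, consensus = hdr("consensus"),
      background = bg, nullMu = as.numeric(hdr("mu")),
      nullBeta = as.numeric(hdr("beta")),
      calibrationN = as.integer(hdr("calibration_n")))
}
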