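#' Parameters for family identification
#'
#' @param evalueMax Retain profile hits with E-value strictly below this
#'   (default 1.0, the classic "E < 1.0" retention rule).
#' @param simMinIdentity Minimum local-alignment identity for the
#'   similarity-search candidate route (default 0.40).
#' @param simMinCoverage Minimum coverage for the similarity route
#'   (default 0.60).
#' @param shortFraction A member's best AP2 hit shorter than this fraction
#'   of the profile length is excluded as `short_domain` (default 0.5).
#' @return A validated parameter list of class `IdentifyParams`.
#' @export
identifyParams <- function(evalueMax = 1.0, simMinIdentity = 0.40,
                           simMinCoverage = 0.60, shortFraction = 0.5) {
  stopifnot(evalueMax > 0,
            simMinIdentity > 0, simMinIdentity <= 1,
            simMinCoverage > 0, simMinCoverage <= 1,
            shortFraction > 0, shortFraction <= 1)
  structure(list(evalueMax = evalueMax, simMinIdentity = simMinIdentity,
                 simMinCoverage = simMinCoverage,
                 shortFraction = shortFraction),
            class = "IdentifyParams")
}

#' Collect family candidates by profile scan and similarity search
#'
#' A protein becomes a candidate when (a) it has at least one profile hit
#' with E-value below `evalueMax`, or (b) a local alignment to any query
#' sequence reaches both `simMinIdentity` identity and `simMinCoverage`
#' coverage. Proteins reached only by route (b) are scanned anyway so every
#' candidate carries its (possibly empty) hit list; route membership is
#' recorded as evidence `"profile"`, `"similarity"` or `"both"`.
#'
#' @param proteome Named [Biostrings::AAStringSet].
#' @param profiles List of calibrated [DomainProfile-class] objects (the
#'   first is taken as the family-defining domain for E-value candidacy).
#' @param querySet Named `AAStringSet` of known family members used as
#'   similarity-search queries.
#' @param params An [identifyParams()] list.
#' @return list with `candidates` (data.frame: `protein_id`, `evidence`)
#'   and `hits` (combined scan hits for candidate proteins).
#' @export
collectCandidates <- function(proteome, profiles, querySet, params = identifyParams()) {
  if (is(profiles, "DomainProfile")) profiles <- list(profiles)
  if (!all(vapply(profiles, isCalibrated, logical(1))))
    stop("all profiles must be calibrated before candidate collection")
  if (!length(querySet)) stop("querySet must be non-empty")
  hits <- scanProteome(profiles, proteome, D = length(proteome))
  sig <- hits[hits$evalue < params$evalueMax, , drop = FALSE]
  profileIds <- unique(sig$protein_id)

  simIds <- character(0)
  qseqs <- as.character(querySet)
  pseqs <- as.character(proteome)
  simHit <- rep(FALSE, length(proteome))
  for (q in qseqs) {
    todo <- which(!simHit)
    if (!length(todo)) break
    mt <- alignToSet(q, setNames(pseqs[todo], names(proteome)[todo]),
                     type = "local")
    simHit[todo] <- mt$identity >= params$simMinIdentity &
      mt$coverage >= params$simMinCoverage
  }
  simIds <- names(proteome)[simHit]

  ids <- union(profileIds, simIds)
  evidence <- ifelse(ids %in% profileIds & ids %in% simIds, "both",
                     ifelse(ids %in% profileIds, "profile", "similarity"))
  list(
    candidates = data.frame(protein_id = ids, evidence = evidence,
                            stringsAsFactors = FALSE),
    hits = hits[hits$protein_id %in% ids, , drop = FALSE]
  )
}

#' Collapse splice variants to one protein per gene
#'
#' Within each gene, the longest candidate protein is kept (ties broken by
#' the lexicographically smallest protein id); the others are recorded as
#' `splice_variant` exclusions.
#'
#' @param candidates Candidate data.frame from [collectCandidates()].
#' @param annot A [GenomeAnnotation-class]; proteins map to genes via
#'   transcript ids.
#' @param proteome The scanned `AAStringSet` (for protein lengths).
#' @return list with `members` (data.frame `protein_id`, `gene_id`,
#'   `evidence`) and `exclusions` (data.frame `protein_id`, `reason`,
#'   `detail`).
#' @export
collapseIsoforms <- function(candidates, annot, proteome) {
  stopifnot(is(annot, "GenomeAnnotation"))
  pid <- candidates$protein_id
  unmapped <- setdiff(pid, names(annot@txToGene))
  if (length(unmapped)) {
    stop("candidate protein(s) not mapped to any gene: ",
         paste(unmapped, collapse = ", "))
  }
  gene <- unname(annot@txToGene[pid])
  len <- Biostrings::width(proteome)[match(pid, names(proteome))]
  df <- data.frame(protein_id = pid, gene_id = gene, len = len,
                   evidence = candidates$evidence, stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, -df$len, df$protein_id), ]
  keep <- !duplicated(df$gene_id)
  members <- df[keep, c("protein_id", "gene_id", "evidence")]
  dropped <- df[!keep, , drop = FALSE]
  exclusions <- data.frame(
    protein_id = dropped$protein_id,
    reason = rep("splice_variant", nrow(dropped)),
    detail = sprintf("isoform of gene %s; kept %s",
                     dropped$gene_id,
                     members$protein_id[match(dropped$gene_id,
                                              members$gene_id)]),
    stringsAsFactors = FALSE)
  rownames(members) <- rownames(exclusions) <- NULL
  list(members = members, exclusions = exclusions)
}

#' Apply the short/divergent/absent-domain exclusion rules
#'
#' Mirrors the manual curation step of published family surveys: a member
#' whose best family-domain hit is absent is excluded as `no_domain`, one
#' whose best hit covers less than `shortFraction` of the profile length as
#' `short_domain`, and one whose best hit misses the E-value threshold as
#' `divergent_domain`. Retained members keep only their significant hits.
#'
#' @param members Member data.frame (from [collapseIsoforms()]).
#' @param hits Scan-hit data.frame for those proteins.
#' @param profiles List of [DomainProfile-class]; the first is the
#'   family-defining domain.
#' @param params [identifyParams()].
#' @return list with `members` (retained, with `n_<domain>` counts and
#'   `best_evalue` columns), `hits` (significant hits of retained members)
#'   and `exclusions`.
#' @export
exclusionFilter <- function(members, hits, profiles, params = identifyParams()) {
  if (is(profiles, "DomainProfile")) profiles <- list(profiles)
  famDomain <- domainName(profiles[[1]])
  L <- length(profiles[[1]])
  reasons <- character(0); who <- character(0); detail <- character(0)
  keep <- logical(nrow(members))
  bestE <- rep(NA_real_, nrow(members))
  for (i in seq_len(nrow(members))) {
    h <- hits[hits$protein_id == members$protein_id[i] &
                hits$domain == famDomain, , drop = FALSE]
    if (!nrow(h)) {
      who <- c(who, members$protein_id[i]); reasons <- c(reasons, "no_domain")
      detail <- c(detail, sprintf("no %s hit from the profile scan", famDomain))
      next
    }
    best <- h[which.max(h$score), ]
    bestE[i] <- best$evalue
    if ((best$end - best$start) < params$shortFraction * L) {
      who <- c(who, members$protein_id[i]); reasons <- c(reasons, "short_domain")
      detail <- c(detail, sprintf("best %s hit covers %d/%d columns",
                                  famDomain, best$end - best$start, L))
      next
    }
    if (best$evalue >= params$evalueMax) {
      who <- c(who, members$protein_id[i])
      reasons <- c(reasons, "divergent_domain")
      detail <- c(detail, sprintf("best %s hit E = %.3g >= %.3g",
                                  famDomain, best$evalue, params$evalueMax))
      next
    }
    keep[i] <- TRUE
  }
  retained <- members[keep, , drop = FALSE]
  retained$best_evalue <- bestE[keep]
  sigHits <- hits[hits$protein_id %in% retained$protein_id &
                    hits$evalue < params$evalueMax, , drop = FALSE]
  for (pf in profiles) {
    dn <- domainName(pf)
    cnt <- table(sigHits$protein_id[sigHits$domain == dn])
    retained[[paste0("n_", dn)]] <-
      as.integer(ifelse(is.na(cnt[retained$protein_id]), 0L,
                        cnt[retained$protein_id]))
  }
  rownames(retained) <- NULL
  list(members = retained, hits = sigHits,
       exclusions = data.frame(protein_id = who, reason = reasons,
                               detail = detail, stringsAsFactors = FALSE))
}

#' Classify a member's domain architecture into a subfamily
#'
#' Two complete (non-truncated) AP2-family domains give `AP2` (three or
#' more give `AP2` with a warning); one AP2 domain plus at least one B3
#' domain gives `RAV`; exactly one AP2 domain and no B3 gives
#' `DREB_ERF_unresolved`, to be resolved to DREB or ERF by phylogenetic
#' anchoring ([labelGroups()]).
#'
#' @param hits Significant hits of one member (data.frame with `domain`,
#'   `truncated`).
#' @param famDomain The family-defining domain name (default `"AP2"`).
#' @param b3Domain The RAV-defining second domain name (default `"B3"`).
#' @return Subfamily label (character scalar).
#' @export
classifyArchitecture <- function(hits, famDomain = "AP2", b3Domain = "B3") {
  nAP2 <- sum(hits$domain == famDomain & !hits$truncated)
  nAP2any <- sum(hits$domain == famDomain)
  nB3 <- sum(hits$domain == b3Domain)
  if (nAP2any == 0) {
    stop("zero ", famDomain,
         " hits: member should have been excluded upstream")
  }
  if (nAP2 >= 3) {
    warning("member has ", nAP2, " complete ", famDomain,
            " domains; classifying as AP2")
    return("AP2")
  }
  if (nAP2 == 2) return("AP2")
  if (nB3 >= 1) return("RAV")
  "DREB_ERF_unresolved"
}

#' Assign chromosomal-order names within subfamilies
#'
#' Within each resolved subfamily, members are sorted by chromosome
#' (natural numeric order on the trailing integer), then gene start, end
#' and gene id, and named `<prefix><SUBFAMILY>-<k>` with k counting from 1
#' -- e.g. `BdDREB-53`.
#'
#' @param members Member data.frame with `subfamily`, `chrom`, `start`,
#'   `end`, `gene_id` columns.
#' @param speciesPrefix Species prefix, e.g. `"Bd"`.
#' @return `members` with an `assigned_name` column, in naming order.
#' @export
assignNames <- function(members, speciesPrefix) {
  if (any(members$subfamily == "DREB_ERF_unresolved")) {
    stop("unresolved DREB/ERF member(s) present; run phylogeny labelling first")
  }
  ord <- order(members$subfamily, chromNaturalOrder(members$chrom),
               members$start, members$end, members$gene_id)
  members <- members[ord, , drop = FALSE]
  k <- stats::ave(seq_len(nrow(members)), members$subfamily,
                  FUN = seq_along)
  members$assigned_name <- sprintf("%s%s-%d", speciesPrefix,
                                   members$subfamily, k)
  rownames(members) <- NULL
  members
}

#' Identify and classify a gene family end to end
#'
#' Runs candidate collection, isoform collapsing, exclusion filtering and
#' architecture classification, and attaches gene coordinates. DREB/ERF
#' resolution and naming are left to the phylogeny stage (or can be forced
#' with `resolveBy` for anchor-free runs).
#'
#' @inheritParams collectCandidates
#' @param annot A [GenomeAnnotation-class].
#' @return list with `members` (data.frame incl. `subfamily`), `hits`,
#'   `exclusions`.
#' @export
identifyFamily <- function(proteome, profiles, querySet, annot,
                           params = identifyParams()) {
  cc <- collectCandidates(proteome, profiles, querySet, params)
  ci <- collapseIsoforms(cc$candidates, annot, proteome)
  ef <- exclusionFilter(ci$members, cc$hits, profiles, params)
  members <- ef$members
  members$subfamily <- vapply(members$protein_id, function(p) {
    classifyArchitecture(ef$hits[ef$hits$protein_id == p, , drop = FALSE],
                         famDomain = domainName(profiles[[1]]),
                         b3Domain = if (base::length(profiles) > 1)
                           domainName(profiles[[2]]) else "B3")
  }, character(1))
  gt <- geneTable(annot)
  gi <- match(members$gene_id, gt$gene_id)
  members$chrom <- gt$chrom[gi]
  members$start <- gt$start[gi]
  members$end <- gt$end[gi]
  members$strand <- gt$strand[gi]
  list(members = members, hits = ef$hits,
       exclusions = rbind(ci$exclusions, ef$exclusions))
}
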