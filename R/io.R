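#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] with the validation the pipeline
#' relies on: identifiers (the first whitespace-delimited token of each
#' header) must be unique, residues are uppercased, terminal stop symbols
#' are stripped, and rare ambiguity codes (B, J, Z, U, O) are mapped to X so
#' downstream scoring sees only the 20 standard residues plus X. Record
#' order is preserved; full headers are kept as the element metadata
#' `description`.
#'
#' @param path Path to a FASTA file.
#' @param gapped Allow the alignment gap character `-` (for seed
#'   alignments). Default FALSE.
#' @return A [Biostrings::AAStringSet] named by identifier.
#' @export
readProteinFasta <- function(path, gapped = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1],
         " precedes the first '>' header in ", path)
  }
  if (!length(nonblank)) {
    return(Biostrings::AAStringSet())
  }
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA: empty identifier in header of ", path)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA identifier(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  x <- toupper(as.character(seqs))
  x <- sub("\\*+$", "", x)
  x <- chartr("BJZUO", "XXXXX", x)
  ok <- paste0(AA_ALPHABET21, collapse = "")
  if (gapped) ok <- paste0(ok, ".-")  # '-' last: literal inside the class
  bad <- grepl(paste0("[^", ok, "]"), x)
  if (any(bad)) {
    stop("invalid residue characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  if (gapped) x <- chartr(".", "-", x)
  out <- Biostrings::AAStringSet(x)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- sub("^\\S+\\s*", "", headers)
  out
}

#' Write a protein FASTA file
#'
#' @param seqs Named [Biostrings::AAStringSet] (or named character vector).
#' @param path Output path.
#' @param width Line wrap width.
#' @return The path, invisibly.
#' @export
writeProteinFasta <- function(seqs, path, width = 60L) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene, mRNA and exon features (via [rtracklayer::import()]) into a
#' [GenomeAnnotation-class]. GFF3's 1-based inclusive coordinates are
#' converted to the package-internal 0-based half-open convention at this
#' boundary; exons are sorted by start within each transcript.
#'
#' @param path Path to a GFF3 file.
#' @return A [GenomeAnnotation-class].
#' @export
readGenomeAnnotation <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- tryCatch(
    read.delim(path, header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) stop("malformed GFF3 in ", path, ": ",
                             conditionMessage(e)))
  if (ncol(raw) < 9) stop("malformed GFF3: fewer than 9 columns in ", path)
  bad <- which(raw[[5]] < raw[[4]])
  if (length(bad)) {
    stop("malformed GFF3: feature end < start at data line ", bad[1],
         " of ", path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  genes <- gr[type == "gene"]
  if (!length(genes)) stop("no gene features found in ", path)
  genes$gene_id <- as.character(genes$ID)

  firstParent <- function(x) {
    p <- as.list(gr$Parent[x])
    vapply(p, function(v) if (length(v)) as.character(v[1]) else NA_character_,
           character(1))
  }
  mrna <- which(type == "mRNA")
  txIds <- ids[mrna]
  txParent <- firstParent(mrna)
  orphan <- is.na(txParent) | !(txParent %in% genes$gene_id)
  if (any(orphan)) {
    stop("orphan mRNA feature(s) without a gene parent: ",
         paste(txIds[orphan], collapse = ", "))
  }
  txToGene <- setNames(txParent, txIds)

  geneStart <- setNames(GenomicRanges::start(genes), genes$gene_id)
  geneEnd <- setNames(GenomicRanges::end(genes), genes$gene_id)

  ex <- which(type == "exon")
  exParent <- firstParent(ex)
  unknown <- !(exParent %in% txIds)
  if (any(unknown)) {
    stop("exon feature(s) with unknown mRNA parent: ",
         paste(unique(exParent[unknown]), collapse = ", "))
  }
  exStart <- GenomicRanges::start(gr)[ex]
  exEnd <- GenomicRanges::end(gr)[ex]
  exonsByTx <- lapply(split(seq_along(ex), exParent), function(i) {
    s <- exStart[i]; e <- exEnd[i]
    o <- order(s)
    cbind(start = s[o] - 1L, end = e[o])  # to 0-based half-open
  })
  for (tx in names(exonsByTx)) {
    g <- txToGene[[tx]]
    exm <- exonsByTx[[tx]]
    if (any(exm[, "start"] < geneStart[[g]] - 1L) ||
        any(exm[, "end"] > geneEnd[[g]])) {
      stop("exon of transcript ", tx, " lies outside the span of gene ", g)
    }
    if (nrow(exm) > 1 && any(exm[-1, "start"] < exm[-nrow(exm), "end"])) {
      stop("overlapping exons within transcript ", tx)
    }
  }
  new("GenomeAnnotation", genes = genes, exonsByTx = exonsByTx,
      txToGene = txToGene)
}

#' Tabular view of gene models
#'
#' @param annot A [GenomeAnnotation-class].
#' @return data.frame with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, plus the transcript count.
#' @export
geneTable <- function(annot) {
  stopifnot(is(annot, "GenomeAnnotation"))
  g <- annot@genes
  ntx <- table(annot@txToGene)
  data.frame(
    gene_id = g$gene_id,
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    n_transcripts = as.integer(ntx[g$gene_id]),
    stringsAsFactors = FALSE
  )
}

#' Intron counts per transcript
#'
#' @param annot A [GenomeAnnotation-class].
#' @return Named integer vector: transcript id -> exon count minus one.
#' @export
intronCounts <- function(annot) {
  stopifnot(is(annot, "GenomeAnnotation"))
  vapply(annot@exonsByTx, function(m) nrow(m) - 1L, integer(1))
}

#' Write gene models as GFF3
#'
#' Inverse of [readGenomeAnnotation()] used by the synthetic-genome
#' generator: emits gene, mRNA and exon features with 1-based inclusive
#' coordinates.
#'
#' @param annot A [GenomeAnnotation-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGff3 <- function(annot, path) {
  stopifnot(is(annot, "GenomeAnnotation"))
  g <- annot@genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  chrom <- as.character(GenomicRanges::seqnames(g))
  strand <- as.character(GenomicRanges::strand(g))
  strand[strand == "*"] <- "+"
  gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
  txByGene <- split(names(annot@txToGene), unname(annot@txToGene))
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    writeLines(sprintf("%s\tap2erf\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       chrom[i], gs[i], ge[i], strand[i], gid), con)
    for (tx in sort(txByGene[[gid]])) {
      exm <- annot@exonsByTx[[tx]]
      writeLines(sprintf("%s\tap2erf\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         chrom[i], min(exm[, "start"]) + 1L, max(exm[, "end"]),
                         strand[i], tx, gid), con)
      for (k in seq_len(nrow(exm))) {
        writeLines(sprintf(
          "%s\tap2erf\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
          chrom[i], exm[k, "start"] + 1L, exm[k, "end"], strand[i],
          tx, k, tx), con)
      }
    }
  }
  invisible(path)
}

#' Read an expression matrix with its sample metadata sidecar
#'
#' The matrix TSV has gene identifiers in the first column and one column
#' per sample; the metadata TSV is keyed by `sample_id` and must describe
#' every sample in the matrix with at least a `condition` column
#' (`timepoint_hours` and `replicate` are optional).
#'
#' @param path Matrix TSV path.
#' @param metadataPath Metadata TSV path.
#' @param units `"counts"` or `"intensity"`; counts must be non-negative.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `value`, the metadata as `colData`, and `units` in `metadata()`.
#' @export
readExpressionTable <- function(path, metadataPath, units = c("counts", "intensity")) {
  units <- match.arg(units)
  tab <- readTsv(path)
  if (ncol(tab) < 2) stop("expression table needs a gene column plus samples")
  geneIds <- as.character(tab[[1]])
  if (anyDuplicated(geneIds)) stop("duplicate gene ids in ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- geneIds
  meta <- readTsv(metadataPath)
  if (!all(c("sample_id", "condition") %in% colnames(meta)))
    stop("metadata must contain sample_id and condition columns")
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing)) {
    stop("sample(s) in matrix missing from metadata: ",
         paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (units == "counts" && any(m < 0, na.rm = TRUE))
    stop("negative values are not valid counts in ", path)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(value = m),
    colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
  S4Vectors::metadata(se)$units <- units
  se
}

#' Write an expression matrix and metadata sidecar
#'
#' @param se SummarizedExperiment with assay `value`.
#' @param path,metadataPath Output TSV paths.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(se, path, metadataPath) {
  m <- SummarizedExperiment::assay(se, "value")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, path)
  writeTsv(as.data.frame(SummarizedExperiment::colData(se)), metadataPath)
  invisible(path)
}

#' Read or write Newick trees
#'
#' Thin wrappers over \pkg{ape} that enforce the package's contracts: leaf
#' labels must be unique and free of Newick-reserved characters (which this
#' writer does not quote), branch lengths survive a round trip to at least
#' six decimals, and integer bootstrap supports ride along as internal-node
#' labels.
#'
#' @param tree An [ape::phylo] object.
#' @param path File path.
#' @return `readNewickTree` returns an [ape::phylo]; `writeNewickTree`
#'   returns `path` invisibly.
#' @export
writeNewickTree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("leaf labels must be unique")
  bad <- grepl("[][(),:;'\" \t]", tree$tip.label)
  if (any(bad)) {
    stop("leaf label(s) contain Newick-reserved characters and cannot be ",
         "written unquoted: ", paste(tree$tip.label[bad], collapse = ", "))
  }
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ape::read.tree(path)
}

#' Read a synteny-block table
#'
#' One row per anchor gene pair; the expected columns are `block_id`,
#' `species_a`, `chrom_a`, `start_a`, `end_a`, `gene_a`, `species_b`,
#' `chrom_b`, `start_b`, `end_b`, `gene_b`. Blocks therefore appear on
#' multiple rows (one per anchor pair) and must have at least one.
#'
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
readSyntenyBlocks <- function(path) {
  need <- c("block_id", "species_a", "chrom_a", "start_a", "end_a", "gene_a",
            "species_b", "chrom_b", "start_b", "end_b", "gene_b")
  tab <- readTsv(path)
  missing <- setdiff(need, colnames(tab))
  if (length(missing)) {
    stop("synteny table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

#' Read a probe-alignment summary table
#'
#' Expected columns: `probe_id`, `gene_id` (may be empty/NA for unaligned
#' probes), `mismatches`, `n_genomic_hits`, `in_exon` (logical or 0/1).
#'
#' @param path TSV path.
#' @return Validated data.frame with `in_exon` coerced to logical.
#' @export
readProbeTable <- function(path) {
  need <- c("probe_id", "gene_id", "mismatches", "n_genomic_hits", "in_exon")
  tab <- readTsv(path)
  missing <- setdiff(need, colnames(tab))
  if (length(missing)) {
    stop("probe table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab$in_exon <- as.logical(tab$in_exon)
  if (any(tab$mismatches < 0, na.rm = TRUE)) stop("negative mismatch count")
  tab
}
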