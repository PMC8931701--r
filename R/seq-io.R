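## Readers/writers for the external formats (FASTA, HMMER3 domtblout, GFF3,
## TPM TSV) and promoter extraction.  FASTA and GFF3 go through Biostrings /
## rtracklayer; the domtblout dialect is parsed here directly.

#' Read a protein or DNA FASTA with integrity checks
#'
#' Wraps [Biostrings::readAAStringSet()] / [Biostrings::readDNAStringSet()],
#' upper-cases sequences, keeps record order, and enforces that ids are
#' unique and non-empty, sequences are non-empty, and the alphabet is valid
#' (20 standard residues plus an optional trailing `*` for protein; ACGTN
#' for DNA).  Only the first whitespace-delimited token of each header is
#' used as the id, as is conventional.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return an [Biostrings::AAStringSet] or [Biostrings::DNAStringSet],
#'   named by record id.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "MKV"), f)
#' readFasta(f, "protein")
#' @export
readFasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  ## read as BStringSet first so alphabet errors are ours, not Biostrings'
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(ids == "")) stop("empty sequence id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sq <- toupper(as.character(raw))
  if (any(nchar(sq) == 0)) stop("empty sequence for id: ",
                                paste(ids[nchar(sq) == 0], collapse = ", "))
  names(sq) <- ids
  if (alphabet == "protein") {
    body <- sub("\\*$", "", sq)
    bad <- grepl(paste0("[^", paste(STD_AA, collapse = ""), "]"), body)
    if (any(bad))
      stop("non-standard residue in protein sequence(s): ",
           paste(ids[bad], collapse = ", "))
    AAStringSet(sq)
  } else {
    bad <- grepl("[^ACGTN]", sq)
    if (any(bad))
      stop("non-ACGTN character in DNA sequence(s): ",
           paste(ids[bad], collapse = ", "))
    DNAStringSet(sq)
  }
}

#' Write sequences to FASTA
#'
#' @param seqs a named XStringSet (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Parse HMMER3 per-domain tabular output (domtblout)
#'
#' One row per domain hit.  Alignment ("ali") coordinates are taken as the
#' authoritative domain location on the protein; model ("hmm") coordinates
#' locate the hit on the profile; the independent (i-)E-value is reported.
#' Envelope coordinates are ignored.
#'
#' @param path path to a `hmmsearch --domtblout` file.
#' @return data.frame with columns `protein_id`, `ali_from`, `ali_to`,
#'   `hmm_from`, `hmm_to`, `evalue`; zero rows for a comment-only file.
#' @export
readDomtblout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  out <- data.frame(protein_id = character(), ali_from = integer(),
                    ali_to = integer(), hmm_from = integer(),
                    hmm_to = integer(), evalue = numeric())
  if (!any(keep)) return(out)
  idx <- which(keep)
  rows <- lapply(seq_along(idx), function(k) {
    f <- strsplit(trimws(lines[idx[k]]), "\\s+")[[1]]
    if (length(f) < 22)
      stop("malformed domtblout row at line ", idx[k],
           " (", length(f), " fields, expected >= 22)")
    num <- suppressWarnings(as.numeric(f[c(13, 16, 17, 18, 19)]))
    if (anyNA(num))
      stop("non-numeric coordinate/E-value field at line ", idx[k])
    data.frame(protein_id = f[1],
               ali_from = as.integer(num[4]), ali_to = as.integer(num[5]),
               hmm_from = as.integer(num[2]), hmm_to = as.integer(num[3]),
               evalue = num[1])
  })
  out <- do.call(rbind, rows)
  bad <- out$ali_from > out$ali_to | out$hmm_from > out$hmm_to | out$evalue < 0
  if (any(bad))
    stop("inconsistent coordinates in domtblout at data row(s): ",
         paste(which(bad), collapse = ", "))
  out
}

#' Write domain hits in the domtblout dialect
#'
#' Emits the 23-column `hmmsearch --domtblout` layout (placeholder values in
#' the columns this pipeline does not use) so that simulated hits can be fed
#' back through [readDomtblout()].
#'
#' @param hits data.frame as returned by [readDomtblout()].
#' @param path output path.
#' @param query model name to record (default `"AP2"`).
#' @return `path`, invisibly.
#' @export
writeDomtblout <- function(hits, path, query = "AP2") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", paste(c("target name", "accession", "tlen",
    "query name", "accession", "qlen", "E-value", "score", "bias", "#", "of",
    "c-Evalue", "i-Evalue", "score", "bias", "from", "to", "from", "to",
    "from", "to", "acc", "description of target"), collapse = " ")), con)
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      writeLines(paste(h$protein_id, "-", 0, query, "PF00847.2", 58,
                       format(h$evalue), 100.0, 0.1, 1, 1,
                       format(h$evalue), format(h$evalue), 100.0, 0.1,
                       h$hmm_from, h$hmm_to, h$ali_from, h$ali_to,
                       h$ali_from, h$ali_to, 0.99, "-"), con)
    }
  }
  invisible(path)
}

#' Partition post-search AP2-domain candidates
#'
#' Applies the E-value cutoff, groups proteins by surviving AP2-domain
#' count, and moves single-domain proteins that also carry a B3 domain to
#' the RAV-excluded group.  The single-domain group (after RAV exclusion)
#' is the ERF-subfamily candidate set all downstream residue analysis
#' operates on.
#'
#' @param hits data.frame of domain hits ([readDomtblout()]).
#' @param proteins optional AAStringSet; when given, hit coordinates are
#'   checked against protein lengths.
#' @param evalueMax independent E-value cutoff (default 0.001).
#' @param b3Ids character vector of protein ids known to carry a B3 domain
#'   (RAV-type); supplied externally.
#' @return list with elements `multi_domain`, `single_domain`,
#'   `rav_excluded` (character vectors of protein ids), `counts` (named
#'   integer vector), and `hits` (the surviving hits of single-domain,
#'   non-RAV proteins).
#' @export
filterCandidates <- function(hits, proteins = NULL, evalueMax = 0.001,
                             b3Ids = character()) {
  stopifnot(is.data.frame(hits))
  if (!is.null(proteins)) {
    w <- setNames(width(proteins), names(proteins))
    known <- hits$protein_id %in% names(w)
    bad <- known & hits$ali_to > w[hits$protein_id]
    if (any(bad))
      stop("domain hit beyond protein length for: ",
           paste(unique(hits$protein_id[bad]), collapse = ", "))
  }
  surv <- hits[hits$evalue <= evalueMax, , drop = FALSE]
  ndom <- table(surv$protein_id)
  multi <- names(ndom)[ndom >= 2]
  single <- names(ndom)[ndom == 1]
  rav <- intersect(single, b3Ids)
  single <- setdiff(single, rav)
  list(multi_domain = multi, single_domain = single, rav_excluded = rav,
       counts = c(multi_domain = length(multi),
                  single_domain = length(single),
                  rav_excluded = length(rav)),
       hits = surv[surv$protein_id %in% single, , drop = FALSE])
}

#' Pick one representative domain hit per protein
#'
#' Lowest independent E-value wins; ties broken by smallest `ali_from`.
#'
#' @param hits data.frame of domain hits.
#' @return data.frame with one row per protein id.
#' @export
selectBestHits <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$protein_id, hits$evalue, hits$ali_from)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$protein_id), , drop = FALSE]
}

#' Extract upstream promoter sequences from a genome and gene models
#'
#' For a plus-strand gene whose anchor base sits at genomic position g the
#' promoter is `genome[g-length .. g-1]`; for a minus-strand gene with
#' anchor at g it is the reverse complement of `genome[g+1 .. g+length]`.
#' Either way the last promoter base is the base adjacent to the anchor
#' (promoter position -1).  Promoters are truncated at chromosome edges
#' with a warning, and the actual width is retained.
#'
#' @param genome a named [Biostrings::DNAStringSet] of chromosomes.
#' @param annotation a [GenomicRanges::GRanges] of gene models (e.g. from
#'   `rtracklayer::import` of a GFF3), or a path to a GFF3 file.  When
#'   `anchor = "translation_start"` and CDS features are present, the
#'   strand-aware first CDS base per gene is the anchor; otherwise the gene
#'   (or range) start is used.
#' @param length promoter length in bp (default 5000).
#' @param anchor `"translation_start"` (default) or `"transcription_start"`.
#' @param geneIds optional ids to restrict to; an unknown id is an error.
#' @return a [PromoterSet].
#' @export
extractPromoters <- function(genome, annotation, length = 5000,
                             anchor = c("translation_start",
                                        "transcription_start"),
                             geneIds = NULL) {
  anchor <- match.arg(anchor)
  if (length <= 0) stop("promoter length must be positive")
  if (is.character(annotation))
    annotation <- rtracklayer::import(annotation, format = "gff3")
  gr <- annotation
  ids <- .grGeneIds(gr)
  hasType <- "type" %in% colnames(mcols(gr))
  genes <- if (hasType && any(gr$type == "gene"))
    gr[gr$type == "gene"] else gr
  geneIdsAll <- .grGeneIds(genes)
  if (is.null(geneIds)) geneIds <- geneIdsAll
  missing <- setdiff(geneIds, geneIdsAll)
  if (length(missing))
    stop("gene id(s) absent from annotation: ",
         paste(missing, collapse = ", "))
  genes <- genes[match(geneIds, geneIdsAll)]

  ## anchor position per gene (1-based genomic coordinate of the first
  ## anchored base, strand-aware)
  anchorPos <- ifelse(as.character(strand(genes)) == "-",
                      end(genes), start(genes))
  if (anchor == "translation_start" && hasType && any(gr$type == "CDS")) {
    cds <- gr[gr$type == "CDS"]
    cdsParent <- .grGeneIds(cds)
    for (i in seq_along(genes)) {
      sel <- cdsParent == geneIds[i]
      if (any(sel)) {
        anchorPos[i] <- if (as.character(strand(genes)[i]) == "-")
          max(end(cds)[sel]) else min(start(cds)[sel])
      }
    }
  }

  chrom <- as.character(seqnames(genes))
  bad <- !chrom %in% names(genome)
  if (any(bad))
    stop("chromosome(s) absent from genome: ",
         paste(unique(chrom[bad]), collapse = ", "))
  chrLen <- setNames(width(genome), names(genome))[chrom]

  seqs <- character(length(genes))
  truncated <- logical(length(genes))
  strands <- as.character(strand(genes))
  strands[!strands %in% c("+", "-")] <- "+"
  for (i in seq_along(genes)) {
    g <- anchorPos[i]
    if (strands[i] == "+") {
      from <- max(1L, g - length); to <- g - 1L
      if (to < from) stop("gene ", geneIds[i], " has no upstream sequence")
      s <- as.character(subseq(genome[[chrom[i]]], from, to))
    } else {
      from <- g + 1L; to <- min(chrLen[i], g + length)
      if (to < from) stop("gene ", geneIds[i], " has no upstream sequence")
      s <- as.character(reverseComplement(subseq(genome[[chrom[i]]], from, to)))
    }
    truncated[i] <- nchar(s) < length
    seqs[i] <- s
  }
  if (any(truncated))
    warning("promoter(s) truncated at chromosome edge: ",
            paste(geneIds[truncated], collapse = ", "))
  names(seqs) <- geneIds
  PromoterSet(seqs, anchor = anchor, strandOfGene = strands,
              requestedLength = length)
}

.grGeneIds <- function(gr) {
  mc <- mcols(gr)
  for (col in c("gene_id", "ID", "Name", "id"))
    if (col %in% colnames(mc) && !anyNA(mc[[col]]))
      return(as.character(mc[[col]]))
  if (!is.null(names(gr)) && !anyNA(names(gr))) return(names(gr))
  ## fall back: ID with NA for non-gene features
  if ("ID" %in% colnames(mc)) return(as.character(mc$ID))
  stop("annotation carries no usable gene identifiers")
}

#' Read a TPM expression matrix from TSV
#'
#' First column is the gene id; remaining column names follow the
#' `<label>_R<replicate>` scheme (e.g. `MatureFlower_R1`), from which the
#' replicate structure is parsed.  Values must be numeric and non-negative.
#'
#' @param path path to the TSV file.
#' @return an [ErfExpressionSet].
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression matrix needs gene ids plus >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene id in expression matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell(s) in expression matrix")
  if (anyNA(m)) stop("missing value(s) in expression matrix")
  if (any(m < 0)) stop("negative TPM value(s) in expression matrix")
  rownames(m) <- ids
  cn <- colnames(m)
  ok <- grepl("^.+_R[0-9]+$", cn)
  if (!all(ok))
    stop("sample name(s) not in '<label>_R<replicate>' scheme: ",
         paste(cn[!ok], collapse = ", "))
  ErfExpressionSet(m,
                   label = sub("_R[0-9]+$", "", cn),
                   replicate = as.integer(sub("^.+_R", "", cn)))
}

#' Write an expression set back to TSV
#' @param x an [ErfExpressionSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  m <- assay(x, "tpm")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
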