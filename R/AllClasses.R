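#' PromoterSet: upstream promoter sequences with extraction metadata
#'
#' Extends [Biostrings::DNAStringSet].  Each element is the promoter of one
#' gene, oriented so that its last base sits at promoter position -1,
#' immediately upstream of the anchor (translation or transcription start).
#' For minus-strand genes the genomic slice has been reverse-complemented,
#' so -1 is still adjacent to the anchor.  Element metadata columns record
#' the anchor convention, the strand of the source gene and the requested
#' length (`width()` gives the actual, possibly edge-truncated, length).
#'
#' @slot .Data inherited from DNAStringSet; names are gene ids.
#' @export
setClass("PromoterSet", contains = "DNAStringSet")

setValidity("PromoterSet", function(object) {
  msg <- character()
  if (length(object)) {
    if (is.null(names(object)) || anyNA(names(object)) || any(names(object) == ""))
      msg <- c(msg, "all promoters must be named by gene id")
    if (anyDuplicated(names(object)))
      msg <- c(msg, "duplicate gene ids in PromoterSet")
    mc <- mcols(object)
    need <- c("anchor", "strand_of_gene", "requested_length")
    if (is.null(mc) || !all(need %in% colnames(mc))) {
      msg <- c(msg, paste("mcols must contain:", paste(need, collapse = ", ")))
    } else {
      if (!all(mc$anchor %in% c("translation_start", "transcription_start")))
        msg <- c(msg, "anchor must be translation_start or transcription_start")
      if (!all(mc$strand_of_gene %in% c("+", "-")))
        msg <- c(msg, "strand_of_gene must be '+' or '-'")
      if (any(mc$requested_length <= 0))
        msg <- c(msg, "requested_length must be positive")
    }
    if (any(BiocGenerics::width(object) == 0))
      msg <- c(msg, "empty promoter sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PromoterSet
#'
#' @param seqs named [Biostrings::DNAStringSet] (or named character vector)
#'   of promoter sequences, one per gene, -1 adjacent to the anchor.
#' @param anchor `"translation_start"` or `"transcription_start"`; recycled.
#' @param strandOfGene `"+"` or `"-"` per gene; recycled.
#' @param requestedLength the promoter length asked for (actual widths may be
#'   shorter at chromosome edges); recycled.
#' @return a `PromoterSet`.
#' @examples
#' PromoterSet(c(g1 = "ACGTACGT"), anchor = "translation_start",
#'             strandOfGene = "+", requestedLength = 8)
#' @export
PromoterSet <- function(seqs, anchor = "translation_start",
                        strandOfGene = "+", requestedLength = NULL) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- DNAStringSet(toupper(seqs))
  if (is.null(requestedLength))
    requestedLength <- if (length(seqs)) max(BiocGenerics::width(seqs)) else 0L
  n <- length(seqs)
  mcols(seqs) <- DataFrame(
    anchor = rep_len(anchor, n),
    strand_of_gene = rep_len(strandOfGene, n),
    requested_length = rep_len(as.integer(requestedLength), n))
  methods::new("PromoterSet", seqs)
}

setMethod("show", "PromoterSet", function(object) {
  cat("PromoterSet of", length(object), "promoters",
      if (length(object)) paste0("(widths ",
        paste(range(BiocGenerics::width(object)), collapse = "-"), " bp)"),
      "\n")
  if (length(object))
    cat("  anchor:", unique(mcols(object)$anchor), "\n")
  invisible(NULL)
})

#' ErfExpressionSet: a TPM expression matrix with sample structure
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single
#' non-negative assay `"tpm"` and a `colData` carrying the sample `label`
#' (organ or stage) and integer `replicate`, every (label, replicate) pair
#' unique.  TPM values over a gene subset need not sum to one million.
#'
#' @export
setClass("ErfExpressionSet", contains = "SummarizedExperiment")

setValidity("ErfExpressionSet", function(object) {
  msg <- character()
  if (!"tpm" %in% SummarizedExperiment::assayNames(object))
    return("assay 'tpm' is required")
  v <- assay(object, "tpm")
  if (anyNA(v) || any(v < 0))
    msg <- c(msg, "TPM values must be finite and non-negative")
  cd <- colData(object)
  if (!all(c("label", "replicate") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'label' and 'replicate'")
  } else if (anyDuplicated(paste(cd$label, cd$replicate)))
    msg <- c(msg, "duplicate (label, replicate) pair")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct an ErfExpressionSet
#'
#' @param tpm numeric matrix, genes x samples, non-negative; rownames are
#'   gene ids.
#' @param label character vector of organ/stage labels, one per column.
#' @param replicate integer replicate index, one per column.
#' @return an `ErfExpressionSet`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), NULL))
#' ErfExpressionSet(m, label = "leaf", replicate = 1:3)
#' @export
ErfExpressionSet <- function(tpm, label, replicate) {
  tpm <- as.matrix(tpm)
  label <- rep_len(label, ncol(tpm))
  replicate <- rep_len(as.integer(replicate), ncol(tpm))
  if (is.null(colnames(tpm)))
    colnames(tpm) <- paste0(label, "_R", replicate)
  se <- SummarizedExperiment(
    assays = list(tpm = tpm),
    colData = DataFrame(label = label, replicate = replicate,
                        row.names = colnames(tpm)))
  methods::new("ErfExpressionSet", se)
}

setMethod("show", "ErfExpressionSet", function(object) {
  cat("ErfExpressionSet:", nrow(object), "genes x", ncol(object), "samples;",
      length(unique(colData(object)$label)), "sample groups\n")
  invisible(NULL)
})

#' Sample labels of an expression set
#' @param x an `ErfExpressionSet`.
#' @return character vector, one label per sample.
#' @export
sampleLabels <- function(x) as.character(colData(x)$label)

#' Per-label replicate-mean TPM
#'
#' Averages replicates within each sample label, giving the genes x labels
#' matrix all downstream expression summaries operate on.
#'
#' @param x an `ErfExpressionSet`.
#' @return numeric matrix, genes x unique labels (in first-appearance order).
#' @export
labelMeans <- function(x) {
  lab <- sampleLabels(x)
  labs <- unique(lab)
  m <- vapply(labs, function(l)
    rowMeans(assay(x, "tpm")[, lab == l, drop = FALSE]),
    numeric(nrow(x)))
  if (nrow(x) == 1L) m <- matrix(m, nrow = 1L,
                                 dimnames = list(rownames(x), labs))
  m
}
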