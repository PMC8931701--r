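## Double-stranded exact-word scanning of promoters for AuxRE/ARF, DRE/CRT
## and GCC-box elements, with negative promoter coordinates (-1 adjacent to
## the anchor), cross-class overlap detection and same-class cluster
## detection.

.DEFAULT_MOTIF_DICTIONARY <- list(
  ARF = c("TGTCTC", "TGTCGG"),
  DRE_CRT = c("ACCGAC", "GCCGAC"),
  GCC = c("GCCGCC"))

#' Default cis-element word dictionary
#'
#' Exact-match words per element class: the canonical AuxRE `TGTCTC` plus
#' `TGTCGG` for ARF; the CCGAC-core words `ACCGAC`/`GCCGAC` for DRE/CRT;
#' `GCCGCC` for the GCC box.  `TGTCGG` is included because its reverse
#' complement shares 5 bp (`CCGAC`) with the DRE/CRT core, the only
#' geometry under which an ARF site can overlap a DRE/CRT site by exactly
#' 5 bp.  Fully user-overridable; every pipeline run logs the dictionary
#' used.
#'
#' @return named list of upper-case DNA words per element class.
#' @export
defaultMotifDictionary <- function() .DEFAULT_MOTIF_DICTIONARY

#' Read a motif dictionary from YAML
#' @param path YAML file mapping element classes to word lists.
#' @return named list of upper-case words.
#' @export
readMotifDictionary <- function(path) {
  d <- read_yaml(path)
  d <- lapply(d, function(w) toupper(as.character(w)))
  .checkDictionary(d)
  d
}

.checkDictionary <- function(motifs) {
  if (!length(motifs) || !sum(lengths(motifs)))
    stop("empty motif dictionary")
  words <- unlist(motifs)
  if (any(nchar(words) < 5))
    stop("dictionary words must be at least 5 bp")
  if (any(grepl("[^ACGT]", words)))
    stop("dictionary words must be ACGT only")
  invisible(motifs)
}

#' Scan promoters for cis-element words on both strands
#'
#' Reports every exact occurrence of every dictionary word on the plus
#' strand of the promoter and (as a minus-strand hit) every occurrence of a
#' word's reverse complement.  Promoter position i (1-based from the left,
#' promoter length L) maps to negative coordinate `i - (L + 1)`, so the
#' base adjacent to the anchor is -1.
#'
#' @param promoters a [PromoterSet], named [Biostrings::DNAStringSet] or
#'   named character vector.
#' @param motifs dictionary (default [defaultMotifDictionary()]).
#' @return data.frame with columns `gene_id`, `element_class`, `strand`,
#'   `neg_start`, `neg_end` (negative, inclusive, `neg_start < neg_end`),
#'   `word`; sorted by gene then `neg_start`.
#' @export
scanElements <- function(promoters, motifs = defaultMotifDictionary()) {
  .checkDictionary(motifs)
  if (methods::is(promoters, "XStringSet")) {
    sq <- as.character(promoters)
  } else sq <- setNames(toupper(as.character(promoters)), names(promoters))
  if (is.null(names(sq)) || any(names(sq) == ""))
    stop("promoters must be named by gene id")
  out <- list()
  for (id in names(sq)) {
    s <- sq[[id]]
    L <- nchar(s)
    for (cls in names(motifs)) for (w in motifs[[cls]]) {
      wlen <- nchar(w)
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") w else
          as.character(reverseComplement(DNAString(w)))
        starts <- .allOccurrences(s, pat)
        if (!length(starts)) next
        out[[length(out) + 1L]] <- data.frame(
          gene_id = id, element_class = cls, strand = strand,
          neg_start = starts - (L + 1L),
          neg_end = starts + wlen - 1L - (L + 1L),
          word = w, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), element_class = character(),
                      strand = character(), neg_start = integer(),
                      neg_end = integer(), word = character()))
  res <- do.call(rbind, out)
  res <- res[order(match(res$gene_id, names(sq)), res$neg_start,
                   res$element_class, res$strand), ]
  rownames(res) <- NULL
  res
}

## all (possibly overlapping) 1-based start positions of fixed word `pat`
## in `s`
.allOccurrences <- function(s, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

#' Cross-class element overlaps within one promoter
#'
#' All unordered pairs of hits from different element classes whose
#' coordinate spans intersect by at least `minOverlap` bp.
#'
#' @param hits data.frame from [scanElements()] for one gene (a multi-gene
#'   table is handled per gene).
#' @param minOverlap minimum intersection size in bp (default 1).
#' @return data.frame with columns `gene_id`, `class1`, `class2`,
#'   `neg_start1`, `neg_end1`, `neg_start2`, `neg_end2`, `strand1`,
#'   `strand2`, `overlap_bp`.
#' @export
findElementOverlaps <- function(hits, minOverlap = 1L) {
  empty <- data.frame(gene_id = character(), class1 = character(),
                      class2 = character(), neg_start1 = integer(),
                      neg_end1 = integer(), neg_start2 = integer(),
                      neg_end2 = integer(), strand1 = character(),
                      strand2 = character(), overlap_bp = integer())
  if (!nrow(hits)) return(empty)
  out <- list()
  for (id in unique(hits$gene_id)) {
    h <- hits[hits$gene_id == id, , drop = FALSE]
    n <- nrow(h)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (h$element_class[i] == h$element_class[j]) next
      ov <- min(h$neg_end[i], h$neg_end[j]) -
        max(h$neg_start[i], h$neg_start[j]) + 1L
      if (ov >= minOverlap)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = id,
          class1 = h$element_class[i], class2 = h$element_class[j],
          neg_start1 = h$neg_start[i], neg_end1 = h$neg_end[i],
          neg_start2 = h$neg_start[j], neg_end2 = h$neg_end[j],
          strand1 = h$strand[i], strand2 = h$strand[j],
          overlap_bp = ov, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Same-class element clusters within a window
#'
#' Greedy left-to-right detection of maximal same-class hit runs of size
#' >= `k` whose total span (leftmost `neg_start` to rightmost `neg_end`)
#' does not exceed `window` bp.
#'
#' @param hits data.frame from [scanElements()].
#' @param k minimum number of sites (default 4).
#' @param window maximum span in bp (default 150).
#' @return data.frame with columns `gene_id`, `element_class`,
#'   `neg_start`, `neg_end`, `count`.
#' @export
findElementClusters <- function(hits, k = 4L, window = 150L) {
  stopifnot(k >= 2, window > 0)
  empty <- data.frame(gene_id = character(), element_class = character(),
                      neg_start = integer(), neg_end = integer(),
                      count = integer())
  if (!nrow(hits)) return(empty)
  out <- list()
  for (id in unique(hits$gene_id)) for (cls in unique(hits$element_class)) {
    h <- hits[hits$gene_id == id & hits$element_class == cls, , drop = FALSE]
    h <- unique(h[, c("neg_start", "neg_end")])
    h <- h[order(h$neg_start, h$neg_end), , drop = FALSE]
    n <- nrow(h)
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n &&
             max(h$neg_end[i:(j + 1)]) - h$neg_start[i] + 1L <= window)
        j <- j + 1L
      if (j - i + 1L >= k) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = id, element_class = cls,
          neg_start = h$neg_start[i], neg_end = max(h$neg_end[i:j]),
          count = j - i + 1L, stringsAsFactors = FALSE)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count distinct element sites per gene and class
#'
#' Counts distinct hit spans per class: a palindromic word hitting the same
#' span on both strands counts once.
#'
#' @param hits data.frame from [scanElements()].
#' @param geneIds optional gene ids to report (genes without hits get
#'   zeros).
#' @param classes element classes to report (default ARF, DRE_CRT, GCC).
#' @return data.frame with one row per gene, one column per class.
#' @export
countElements <- function(hits, geneIds = unique(hits$gene_id),
                          classes = ELEMENT_CLASSES) {
  cnt <- matrix(0L, nrow = length(geneIds), ncol = length(classes),
                dimnames = list(geneIds, classes))
  if (nrow(hits)) {
    d <- unique(hits[, c("gene_id", "element_class", "neg_start", "neg_end")])
    d <- d[d$gene_id %in% geneIds & d$element_class %in% classes, ,
           drop = FALSE]
    if (nrow(d)) {
      t <- table(d$gene_id, d$element_class)
      cnt[rownames(t), colnames(t)] <- t
    }
  }
  data.frame(gene_id = geneIds, cnt, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}
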