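## EAR (LxLxL, DLNxxP) and EDLL protein-motif detection and composite
## strong-repressor typing.  'x' matches any of the 20 standard residues;
## all occurrences, including overlapping ones, are reported.

.MOTIF_PATTERNS <- list(
  LxLxL = list(regex = "L.L.L", len = 5L),
  DLNxxP = list(regex = "DLN..P", len = 6L),
  EDLL = list(regex = "E....D...L...L", len = 14L))

#' Find EAR/EDLL motifs in protein sequences
#'
#' Scans each protein left to right for the requested motif classes:
#' `LxLxL` (L,any,L,any,L), `DLNxxP` (D,L,N,any,any,P) and `EDLL`
#' (ExxxxDxxxLxxxL).  Overlapping occurrences are all reported.  The
#' terminal call is `N` when the hit's midpoint lies in the first half of
#' the protein, else `C`.
#'
#' @param proteins a named [Biostrings::AAStringSet] (or named character
#'   vector of protein sequences).
#' @param motifClass character vector among `"LxLxL"`, `"DLNxxP"`,
#'   `"EDLL"`; default all three.
#' @return data.frame with columns `protein_id`, `motif_class`, `start`,
#'   `end` (1-based inclusive), `matched_text`, `terminal`.
#' @examples
#' findProteinMotifs(c(p = "MADLNRRPQ"), "DLNxxP")
#' @export
findProteinMotifs <- function(proteins,
                              motifClass = names(.MOTIF_PATTERNS)) {
  motifClass <- match.arg(motifClass, names(.MOTIF_PATTERNS),
                          several.ok = TRUE)
  if (methods::is(proteins, "XStringSet")) {
    sq <- as.character(proteins)
  } else sq <- setNames(toupper(as.character(proteins)), names(proteins))
  if (is.null(names(sq)) || any(names(sq) == ""))
    stop("proteins must be named")
  bad <- grepl(paste0("[^", paste(STD_AA, collapse = ""), "]"),
               sub("\\*$", "", sq))
  if (any(bad))
    stop("non-protein alphabet in: ", paste(names(sq)[bad], collapse = ", "))
  anyAA <- paste0("[", paste(STD_AA, collapse = ""), "]")
  out <- list()
  for (id in names(sq)) {
    s <- sq[[id]]
    half <- nchar(s) / 2
    for (mc in motifClass) {
      pat <- .MOTIF_PATTERNS[[mc]]
      ## lookahead so overlapping matches are found; '.' restricted to the
      ## 20 standard residues
      rx <- paste0("(?=(", gsub(".", anyAA, pat$regex, fixed = TRUE), "))")
      m <- gregexpr(rx, s, perl = TRUE)[[1]]
      if (m[1] == -1) next
      starts <- as.integer(m)
      out[[length(out) + 1L]] <- data.frame(
        protein_id = id, motif_class = mc,
        start = starts, end = starts + pat$len - 1L,
        matched_text = substring(s, starts, starts + pat$len - 1L),
        terminal = ifelse((starts + starts + pat$len - 1L) / 2 <= half,
                          "N", "C"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(protein_id = character(), motif_class = character(),
                      start = integer(), end = integer(),
                      matched_text = character(), terminal = character()))
  res <- do.call(rbind, out)
  res <- res[order(match(res$protein_id, names(sq)), res$start, res$motif_class), ]
  rownames(res) <- NULL
  res
}

#' Classify the repressor status of one protein from its motif hits
#'
#' `composite_strong` when a DLNxxP hit and an LxLxL hit overlap or lie
#' within `maxGap` residues of each other (the two EAR patterns joined into
#' one strong repressive motif); otherwise `EAR_containing` when any EAR
#' hit exists; otherwise `none`.  EDLL hits do not affect the status.
#'
#' @param hits data.frame from [findProteinMotifs()], all rows from one
#'   protein.
#' @param maxGap maximum residue gap between the DLNxxP and LxLxL spans for
#'   the composite call (default 2).
#' @return data.frame with one row: `protein_id`, `status`, `n_LxLxL`,
#'   `n_DLNxxP`.
#' @export
classifyRepressor <- function(hits, maxGap = 2L) {
  ids <- unique(hits$protein_id)
  if (length(ids) > 1)
    stop("hits from multiple proteins: ", paste(ids, collapse = ", "))
  ## counts over distinct spans (identical spans merged)
  distinct <- function(mc) {
    h <- hits[hits$motif_class == mc, c("start", "end"), drop = FALSE]
    unique(h)
  }
  lx <- distinct("LxLxL")
  dl <- distinct("DLNxxP")
  status <- "none"
  if (nrow(lx) + nrow(dl) > 0) status <- "EAR_containing"
  if (nrow(lx) && nrow(dl)) {
    for (i in seq_len(nrow(dl))) for (j in seq_len(nrow(lx))) {
      gap <- max(lx$start[j] - dl$end[i] - 1L, dl$start[i] - lx$end[j] - 1L)
      if (gap <= maxGap) { status <- "composite_strong"; break }
    }
  }
  data.frame(protein_id = if (length(ids)) ids else NA_character_,
             status = status,
             n_LxLxL = nrow(lx), n_DLNxxP = nrow(dl),
             stringsAsFactors = FALSE)
}

#' Repressor status for every protein in a hit table
#'
#' @param hits data.frame from [findProteinMotifs()] (may span proteins).
#' @param proteinIds optional ids to report on (proteins without hits get
#'   status `none`).
#' @param maxGap see [classifyRepressor()].
#' @return data.frame, one row per protein.
#' @export
classifyRepressors <- function(hits, proteinIds = unique(hits$protein_id),
                               maxGap = 2L) {
  rows <- lapply(proteinIds, function(id)
    classifyRepressor(hits[hits$protein_id == id, , drop = FALSE],
                      maxGap = maxGap))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(protein_id = character(), status = character(),
                      n_LxLxL = integer(), n_DLNxxP = integer())
  out$protein_id <- proteinIds
  out
}
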