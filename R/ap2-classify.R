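## Diagnostic-residue extraction from AP2 domains and residue-based
## DREB/ERF subfamily classification.
##
## Positions 9/13/14/15/19 are counted "of the AP2 domain", i.e. in profile
## model columns, so an N-terminally truncated alignment still yields the
## right residues.  A calibration reference maps that numbering onto the
## model in use.

KEY_POSITIONS <- c(9L, 13L, 14L, 15L, 19L)

DREB_POS14 <- c("V", "I")
ERF_POS14 <- c("A", "T", "S", "G", "E")

#' Calibrate AP2-domain position numbering against a reference protein
#'
#' Finds the integer offset `delta` such that domain position `p`
#' corresponds to model column `p + delta`, by exhaustive search over
#' `[-5, 5]` against a reference protein whose diagnostic residues are
#' known (e.g. a canonical DREB with V14/E19).
#'
#' @param reference named character/AAStringSet of length 1, or a plain
#'   sequence string: the reference protein.
#' @param referenceHit one-row data.frame with the reference's domain hit
#'   (`ali_from`, `ali_to`, `hmm_from`, `hmm_to`).
#' @param expected named character vector of expected residues, names among
#'   `pos9, pos13, pos14, pos15, pos19`; `'-'` entries are ignored.
#' @return the offset (integer scalar).
#' @export
calibrateOffset <- function(reference, referenceHit, expected) {
  seqc <- .asSeqChar(reference)
  exp <- expected[expected != "-"]
  if (!length(exp)) stop("calibration needs at least one expected residue")
  pos <- as.integer(sub("^pos", "", names(exp)))
  if (anyNA(pos)) stop("expected residue names must be 'pos<k>'")
  for (delta in -5:5) {
    kr <- .residuesAt(seqc, referenceHit, pos + delta)
    if (all(kr == unname(exp))) return(delta)
  }
  stop("calibration failure: no offset in [-5, 5] reproduces the expected ",
       "residues (check the reference or its domain hit)")
}

## residues of `seqc` (character scalar) at model columns `cols` under a
## gapless ali/hmm mapping; '-' outside the aligned span
.residuesAt <- function(seqc, hit, cols) {
  n <- nchar(seqc)
  vapply(cols, function(m) {
    if (m < hit$hmm_from || m > hit$hmm_to) return("-")
    i <- hit$ali_from + (m - hit$hmm_from)
    if (i < 1 || i > n)
      stop("model column ", m, " maps outside the protein (index ", i, ")")
    substr(seqc, i, i)
  }, character(1))
}

.asSeqChar <- function(x) {
  if (methods::is(x, "XStringSet")) as.character(x[[1]])
  else if (methods::is(x, "XString")) as.character(x)
  else as.character(x)[1]
}

#' Extract the diagnostic AP2-domain residues
#'
#' For each protein, reads the residues aligned to model columns
#' `p + offset` for domain positions p = 9, 13, 14, 15, 19 under the
#' gapless mapping `protein[ali_from + (p + offset - hmm_from)]`.  A
#' position outside the aligned span yields `'-'`.
#'
#' @param proteins a named [Biostrings::AAStringSet].
#' @param hits data.frame of domain hits, one row per protein (see
#'   [selectBestHits()]).
#' @param offset calibration offset from [calibrateOffset()] (default 0).
#' @return data.frame with columns `protein_id`, `pos9`, `pos13`, `pos14`,
#'   `pos15`, `pos19`.
#' @export
extractKeyResidues <- function(proteins, hits, offset = 0L) {
  stopifnot(is.data.frame(hits))
  if (anyDuplicated(hits$protein_id))
    stop("one hit per protein required; see selectBestHits()")
  missing <- setdiff(hits$protein_id, names(proteins))
  if (length(missing))
    stop("hit(s) for unknown protein(s): ", paste(missing, collapse = ", "))
  res <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    r <- .residuesAt(as.character(proteins[[h$protein_id]]), h,
                     KEY_POSITIONS + offset)
    c(protein_id = h$protein_id, setNames(r, paste0("pos", KEY_POSITIONS)))
  })
  df <- as.data.frame(do.call(rbind, res), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Classify proteins into the DREB or ERF subfamily
#'
#' Purely residue-based: position 14 in \{V, I\} is DREB (isoleucine being a
#' conservative valine substitution), position 14 in \{A, T, S, G, E\} is
#' ERF; anything else is `unclassified` with a warning.  `rule_fired`
#' records the (pos14, pos19) pair, e.g. `"V14E19"`.
#'
#' @param keyResidues data.frame from [extractKeyResidues()] (columns
#'   `protein_id`, `pos14`, `pos19` required).
#' @return data.frame with columns `protein_id`, `subfamily`, `rule_fired`,
#'   `pos14`, `pos19`.
#' @export
classifySubfamily <- function(keyResidues) {
  kr <- keyResidues
  if (any(kr$pos14 == "-"))
    stop("position 14 outside the aligned domain span for: ",
         paste(kr$protein_id[kr$pos14 == "-"], collapse = ", "),
         " (domain truncation)")
  subfam <- ifelse(kr$pos14 %in% DREB_POS14, "DREB",
                   ifelse(kr$pos14 %in% ERF_POS14, "ERF", "unclassified"))
  if (any(subfam == "unclassified"))
    warning("residue at position 14 outside both rule tables for: ",
            paste(kr$protein_id[subfam == "unclassified"], collapse = ", "))
  data.frame(protein_id = kr$protein_id,
             subfamily = subfam,
             rule_fired = ifelse(subfam == "unclassified", "none",
                                 paste0(kr$pos14, "14", kr$pos19, "19")),
             pos14 = kr$pos14, pos19 = kr$pos19,
             stringsAsFactors = FALSE)
}

## physicochemical annotation of the residues occurring at positions 14/19
## across the subfamilies; three-part lookup: character, polarity, chemical
## structure
.RESIDUE_PROPS <- data.frame(
  residue = c("V", "I", "L", "A", "T", "S", "G", "E", "D", "N", "Q", "H", "Y"),
  character = c("hydrophobic", "hydrophobic", "hydrophobic", "neutral",
                "neutral", "neutral", "neutral", "hydrophilic", "hydrophilic",
                "hydrophilic", "hydrophilic", "hydrophilic", "hydrophilic"),
  polarity = c("non-polarity", "non-polarity", "non-polarity", "non-polarity",
               "polarity without charge", "polarity without charge",
               "polarity without charge", "polarity with negative charge",
               "polarity with negative charge", "polarity without charge",
               "polarity without charge", "polarity with positive charge",
               "polarity without charge"),
  chemical_structure = c("aliphatic", "aliphatic", "aliphatic", "aliphatic",
                         "aliphatic", "aliphatic", "aliphatic", "aliphatic",
                         "aliphatic", "aliphatic", "aliphatic", "heterocycle",
                         "aromatic"),
  stringsAsFactors = FALSE)

#' Physicochemical properties of a diagnostic residue
#'
#' Returns the (character, polarity, chemical structure) triple for the
#' residues tabulated at the diagnostic positions; residues not tabulated
#' yield an explicit `"not tabulated"` marker rather than a guess.
#'
#' @param residue character vector of one-letter amino acid codes.
#' @return data.frame with columns `residue`, `character`, `polarity`,
#'   `chemical_structure`.
#' @examples
#' residueProperties(c("V", "H", "Y"))
#' @export
residueProperties <- function(residue) {
  residue <- toupper(as.character(residue))
  bad <- !residue %in% STD_AA
  if (any(bad)) stop("not an amino acid code: ",
                     paste(unique(residue[bad]), collapse = ", "))
  i <- match(residue, .RESIDUE_PROPS$residue)
  out <- data.frame(residue = residue,
                    character = .RESIDUE_PROPS$character[i],
                    polarity = .RESIDUE_PROPS$polarity[i],
                    chemical_structure = .RESIDUE_PROPS$chemical_structure[i],
                    stringsAsFactors = FALSE)
  out[is.na(i), c("character", "polarity", "chemical_structure")] <-
    "not tabulated"
  out
}

#' Back-derive the codon of a protein position from its CDS
#'
#' Returns the RNA codon (`T` transcribed to `U`) at protein position `i`,
#' after checking that the codon actually translates (standard code) to the
#' residue the protein carries there.
#'
#' @param cds CDS sequence (DNAString(Set) element or character).
#' @param protein matching protein sequence.
#' @param proteinIndex 1-based residue position.
#' @return RNA codon as a character scalar, e.g. `"GUU"`.
#' @examples
#' codonAt("GTTGAA", "VE", 1)  # "GUU"
#' @export
codonAt <- function(cds, protein, proteinIndex) {
  cdsc <- toupper(.asSeqChar(cds))
  protc <- toupper(.asSeqChar(protein))
  i <- as.integer(proteinIndex)
  if (i < 1 || i > nchar(protc)) stop("protein index out of range")
  if (nchar(cdsc) < 3 * i)
    stop("CDS shorter than 3 x protein position ", i)
  codon <- substr(cdsc, 3 * (i - 1) + 1, 3 * i)
  aa <- as.character(translate(DNAString(codon)))
  if (aa != substr(protc, i, i))
    stop("CDS/protein mismatch at position ", i, ": codon ", codon,
         " translates to ", aa, ", protein has ", substr(protc, i, i))
  chartr("T", "U", codon)
}

#' Tally (pos14, pos19) residue pairs by subfamily
#'
#' Reproduces the family summary layout: per subfamily, the count of
#' proteins carrying each (position 14, position 19) residue pair, sorted
#' by count descending.
#'
#' @param calls data.frame from [classifySubfamily()].
#' @return data.frame with columns `subfamily`, `pos14`, `pos19`, `n`.
#' @export
summarizeFamily <- function(calls) {
  if (!nrow(calls))
    return(data.frame(subfamily = character(), pos14 = character(),
                      pos19 = character(), n = integer()))
  agg <- stats::aggregate(list(n = seq_len(nrow(calls))),
                          by = list(subfamily = calls$subfamily,
                                    pos14 = calls$pos14,
                                    pos19 = calls$pos19),
                          FUN = length)
  agg <- agg[order(agg$subfamily, -agg$n, agg$pos14, agg$pos19), ]
  rownames(agg) <- NULL
  agg
}
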