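## Brute-force oracles kept deliberately independent of the package's
## scanning code paths: per-window character comparisons, no regex.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

## protein-motif oracle: slide a window and compare residue-by-residue
## against the pattern spelled as a list of allowed-character sets
naiveMotifScan <- function(seq, motifClass) {
  sets <- switch(motifClass,
    LxLxL = list("L", AA20, "L", AA20, "L"),
    DLNxxP = list("D", "L", "N", AA20, AA20, "P"),
    EDLL = c(list("E"), rep(list(AA20), 4), list("D"), rep(list(AA20), 3),
             list("L"), rep(list(AA20), 3), list("L")))
  chars <- strsplit(seq, "")[[1]]
  w <- length(sets)
  starts <- integer()
  for (s in seq_len(max(0L, length(chars) - w + 1L))) {
    ok <- TRUE
    for (k in seq_len(w))
      if (!(chars[s + k - 1L] %in% sets[[k]])) { ok <- FALSE; break }
    if (ok) starts <- c(starts, s)
  }
  starts
}

## hand-rolled reverse complement (no Biostrings)
rcomp <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

## promoter-element oracle: substring equality at every offset, both
## strands, negative coordinates by direct arithmetic
naiveElementScan <- function(seq, motifs) {
  L <- nchar(seq)
  out <- NULL
  for (cls in names(motifs)) for (w in motifs[[cls]]) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") w else rcomp(w)
      wl <- nchar(pat)
      for (s in seq_len(max(0L, L - wl + 1L))) {
        if (substr(seq, s, s + wl - 1L) == pat)
          out <- rbind(out, data.frame(
            element_class = cls, strand = strand,
            neg_start = s - (L + 1L), neg_end = s + wl - 1L - (L + 1L),
            word = w, stringsAsFactors = FALSE))
      }
    }
  }
  out
}

randomProteinSeq <- function(n) paste(sample(AA20, n, TRUE), collapse = "")
randomDnaSeq <- function(n)
  paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")

## hand-written regulatory truth tables, one per hormone axis:
## (trend, element present?) -> mode
iaaTruthTable <- data.frame(
  trend = c("up", "up", "down", "down", "flat", "flat"),
  present = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
  mode = c("direct_induction", "indirect_induction",
           "direct_repression", "indirect_repression", "none", "none"),
  stringsAsFactors = FALSE)
etTruthTable <- iaaTruthTable  # same four-way logic on DRE/CRT + GCC

lookupMode <- function(table, trend, present)
  table$mode[table$trend == trend & table$present == present]
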