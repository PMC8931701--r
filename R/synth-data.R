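## Synthetic proteins, promoters and expression matrices with planted,
## machine-readable ground truth.  Backgrounds are rejected and re-drawn
## (bounded retries) whenever they contain motif patterns or dictionary
## words that were not planted, so planted-truth tests are exact.

.MAX_REDRAWS <- 1000L

#' Default fruit stage-to-phase mapping
#'
#' Four development stages spanning 8-28 days post anthesis and four
#' ripening stages spanning 28-53 DPA, sharing the 28 DPA boundary stage.
#' The format expected by [phaseTrend()] and [simulateExpression()].
#'
#' @format named list of ordered stage-label vectors.
#' @export
DEFAULT_STAGES <- list(
  development = c("8DPA", "14DPA", "21DPA", "28DPA"),
  ripening = c("28DPA", "35DPA", "42DPA", "53DPA"))

#' Random protein specifications with known subfamily labels
#'
#' Draws diagnostic-residue signatures from the residue pools observed in
#' the two subfamilies (DREB: position 14 V/I; ERF: position 14 A/T/S/G/E)
#' plus a small fraction of out-of-table signatures labelled
#' `unclassified`, and assigns EAR/EDLL motifs to a fraction of proteins.
#' The label is fixed at draw time and recorded as planted truth.
#'
#' @param n number of proteins.
#' @param pUnclassified fraction given a position-14 residue outside both
#'   subfamily tables (default 0.05).
#' @param pMotif fraction given one planted motif (default 0.4).
#' @param length protein length (default 200).
#' @return data.frame of specs for [simulateProteins()], with the planted
#'   `subfamily` label column.
#' @export
randomProteinSpecs <- function(n, pUnclassified = 0.05, pMotif = 0.4,
                               length = 200L) {
  subfam <- sample(c("DREB", "ERF", "unclassified"), n, replace = TRUE,
                   prob = c((1 - pUnclassified) / 2,
                            (1 - pUnclassified) / 2, pUnclassified))
  pos14 <- ifelse(subfam == "DREB",
                  sample(DREB_POS14, n, replace = TRUE,
                         prob = c(0.9, 0.1)),
                  ifelse(subfam == "ERF",
                         sample(ERF_POS14, n, replace = TRUE,
                                prob = c(0.85, 0.04, 0.07, 0.02, 0.02)),
                         sample(c("K", "R", "M"), n, replace = TRUE)))
  pos19 <- ifelse(subfam == "DREB",
                  sample(c("E", "D", "N", "Q", "H", "L", "A", "V"), n,
                         replace = TRUE,
                         prob = c(30, 4, 1, 4, 6, 10, 1, 1) / 57),
                  sample(c("D", "Y", "N"), n, replace = TRUE,
                         prob = c(0.9, 0.05, 0.05)))
  pos9 <- ifelse(subfam == "DREB",
                 sample(c("S", "H", "N", "K", "T", "Q", "I", "A", "P", "D"),
                        n, replace = TRUE),
                 sample(c("P", "K", "T", "Q", "E"), n, replace = TRUE,
                        prob = c(0.8, 0.05, 0.05, 0.05, 0.05)))
  pos13 <- ifelse(subfam == "DREB", "W",
                  sample(c("Y", "F", "W"), n, replace = TRUE))
  pos15 <- ifelse(subfam == "DREB",
                  sample(c("S", "A", "C"), n, replace = TRUE), "A")
  motifs <- ifelse(runif(n) < pMotif,
                   sample(c("LxLxL:N", "LxLxL:C", "DLNxxP:C", "EDLL:C",
                            "DLNxxP:C;LxLxL:C"), n, replace = TRUE),
                   "")
  data.frame(protein_id = sprintf("synthP%03d", seq_len(n)),
             pos9 = pos9, pos13 = pos13, pos14 = pos14, pos15 = pos15,
             pos19 = pos19, subfamily = subfam, motifs = motifs,
             length = length, stringsAsFactors = FALSE)
}

## instantiate one motif pattern with wildcards drawn from `pool`,
## avoiding the pattern's own anchor letters so planting cannot create
## extra overlapping matches by itself
.motifInstance <- function(motifClass) {
  pat <- .MOTIF_PATTERNS[[motifClass]]
  anchors <- unique(strsplit(gsub("[^A-Z]", "", pat$regex), "")[[1]])
  pool <- setdiff(STD_AA, c(anchors, "L", "D", "N", "P", "E"))
  chars <- strsplit(pat$regex, "")[[1]]
  paste(vapply(chars, function(ch)
    if (ch == ".") sample(pool, 1) else ch, character(1)), collapse = "")
}

.parseMotifSpec <- function(spec) {
  if (is.na(spec) || spec == "") return(NULL)
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  do.call(rbind, lapply(parts, function(p) {
    bits <- strsplit(p, ":", fixed = TRUE)[[1]]
    data.frame(motif_class = bits[1],
               where = if (length(bits) > 1) bits[2] else "any",
               stringsAsFactors = FALSE)
  }))
}

#' Simulate proteins with planted AP2 domains and motifs
#'
#' Each protein is a random background sequence carrying a 58-residue
#' AP2-like block whose diagnostic positions (9/13/14/15/19) hold the
#' requested residues, plus optionally planted EAR/EDLL motifs.  A
#' matching domain-hit table (alignment and model coordinates) is emitted
#' so no HMM search is needed downstream.  Backgrounds containing
#' unplanted motif occurrences are re-drawn (up to 1000 times), so the
#' planted motif spans are exactly the detectable ones.
#'
#' @param specs data.frame with columns `protein_id`, `pos9`, `pos13`,
#'   `pos14`, `pos15`, `pos19`, optional `motifs`
#'   (semicolon-separated `"<class>[:N|:C|:<start>]"` entries, `""` for
#'   none), optional `length` (>= 80, default 200) and optional
#'   `subfamily` (planted label, carried into the truth table).  See
#'   [randomProteinSpecs()].
#' @param seed RNG seed.
#' @return list with `proteins` ([Biostrings::AAStringSet]), `hits`
#'   (domain-hit data.frame), and `truth` (list with `residues`,
#'   `domains`, `motifs` data.frames).
#' @export
simulateProteins <- function(specs, seed = 1L) {
  set.seed(seed)
  if (is.null(specs$motifs)) specs$motifs <- ""
  if (is.null(specs$length)) specs$length <- 200L
  if (any(specs$length < 80)) stop("protein length must be >= 80")
  if (is.null(specs$subfamily)) specs$subfamily <- NA_character_
  seqs <- character(nrow(specs))
  hits <- vector("list", nrow(specs))
  motifTruth <- list()
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    len <- as.integer(sp$length)
    wanted <- .parseMotifSpec(sp$motifs)
    for (try in seq_len(.MAX_REDRAWS)) {
      ## AP2-like block with the diagnostic residues planted
      dom <- sample(STD_AA, 58, replace = TRUE)
      dom[KEY_POSITIONS] <- c(sp$pos9, sp$pos13, sp$pos14, sp$pos15,
                              sp$pos19)
      domStart <- sample.int(len - 58L + 1L, 1)
      body <- sample(STD_AA, len, replace = TRUE)
      body[domStart:(domStart + 57L)] <- dom
      ## plant motifs outside the domain
      planted <- NULL
      ok <- TRUE
      occupied <- cbind(domStart, domStart + 57L)
      if (!is.null(wanted)) {
        for (k in seq_len(nrow(wanted))) {
          mlen <- .MOTIF_PATTERNS[[wanted$motif_class[k]]]$len
          cand <- switch(wanted$where[k],
                         N = seq_len(max(1L, ceiling(len / 2) - mlen + 1L)),
                         C = seq(ceiling(len / 2) + 1L, len - mlen + 1L),
                         any = seq_len(len - mlen + 1L),
                         as.integer(wanted$where[k]))
          free <- cand[vapply(cand, function(s) {
            all(s + mlen - 1L < occupied[, 1] | s > occupied[, 2])
          }, logical(1))]
          if (!length(free)) {
            if (length(cand) == 1)
              stop("motif ", wanted$motif_class[k],
                   " cannot be planted at requested position for ",
                   sp$protein_id, " (overlaps a planted span)")
            ok <- FALSE; break
          }
          s <- if (length(free) == 1) free else sample(free, 1)
          inst <- .motifInstance(wanted$motif_class[k])
          body[s:(s + mlen - 1L)] <- strsplit(inst, "")[[1]]
          occupied <- rbind(occupied, c(s, s + mlen - 1L))
          planted <- rbind(planted, data.frame(
            protein_id = sp$protein_id,
            motif_class = wanted$motif_class[k],
            start = s, end = s + mlen - 1L,
            matched_text = inst, stringsAsFactors = FALSE))
        }
        if (!ok) next
      }
      sq <- paste(body, collapse = "")
      ## scrub: every detectable motif occurrence must have been planted
      found <- findProteinMotifs(setNames(sq, sp$protein_id))
      want <- if (is.null(planted))
        character() else paste(planted$motif_class, planted$start)
      got <- paste(found$motif_class, found$start)
      if (setequal(got, want) && length(got) == length(want)) {
        seqs[i] <- sq
        hits[[i]] <- data.frame(protein_id = sp$protein_id,
                                ali_from = domStart,
                                ali_to = domStart + 57L,
                                hmm_from = 1L, hmm_to = 58L,
                                evalue = 1e-30,
                                stringsAsFactors = FALSE)
        if (!is.null(planted))
          motifTruth[[length(motifTruth) + 1L]] <- planted
        break
      }
      if (try == .MAX_REDRAWS)
        stop("could not draw a clean background for ", sp$protein_id)
    }
  }
  names(seqs) <- specs$protein_id
  truthMotifs <- if (length(motifTruth)) do.call(rbind, motifTruth) else
    data.frame(protein_id = character(), motif_class = character(),
               start = integer(), end = integer(),
               matched_text = character())
  hits <- do.call(rbind, hits)
  list(proteins = AAStringSet(seqs),
       hits = hits,
       truth = list(
         residues = data.frame(protein_id = specs$protein_id,
                               pos9 = specs$pos9, pos13 = specs$pos13,
                               pos14 = specs$pos14, pos15 = specs$pos15,
                               pos19 = specs$pos19,
                               subfamily = specs$subfamily,
                               stringsAsFactors = FALSE),
         domains = hits,
         motifs = truthMotifs))
}

#' Random promoter specifications
#'
#' Gives each gene 0-6 planted elements (random class, strand and
#' position) and a fraction of genes one engineered ARF/DRE 5-bp overlap.
#'
#' @param n number of promoters.
#' @param length promoter length (default 5000).
#' @param maxElements maximum planted elements per gene (default 6).
#' @param pOverlap fraction of genes with an engineered overlap
#'   (default 0.2).
#' @return list of per-gene specs for [simulatePromoters()].
#' @export
randomPromoterSpecs <- function(n, length = 5000L, maxElements = 6L,
                                pOverlap = 0.2) {
  ## well-separated placement slots so planted spans never collide
  slots <- seq(10L, length - 20L, by = 12L)
  lapply(seq_len(n), function(i) {
    nel <- sample(0:maxElements, 1)
    el <- NULL
    if (nel > 0)
      el <- data.frame(
        element_class = sample(ELEMENT_CLASSES, nel, replace = TRUE),
        strand = sample(c("+", "-"), nel, replace = TRUE),
        neg_start = sort(sample(slots, nel)) - (length + 1L),
        stringsAsFactors = FALSE)
    list(gene_id = sprintf("synthG%03d", i),
         elements = el,
         n_overlaps = as.integer(runif(1) < pOverlap))
  })
}

#' Simulate promoters with planted cis-elements and engineered overlaps
#'
#' Builds random-background promoters, writes the requested element words
#' (or their reverse complements, for minus-strand hits) at the requested
#' negative coordinates, and optionally plants engineered ARF/DRE 5-bp
#' overlaps using the `ACCGACA` construction (a plus-strand `ACCGAC`
#' DRE/CRT site whose last five bases are shared with a minus-strand
#' `TGTCGG` ARF site).  Backgrounds with spurious dictionary-word
#' occurrences are re-drawn (up to 1000 times); colliding planted spans
#' are an error.
#'
#' @param specs list of per-gene lists with fields `gene_id`, `elements`
#'   (data.frame `element_class`, `strand`, `neg_start`, optional `word`;
#'   or NULL) and `n_overlaps` (engineered overlaps, default 0).  See
#'   [randomPromoterSpecs()].
#' @param length promoter length (default 5000).
#' @param motifs word dictionary (default [defaultMotifDictionary()]).
#' @param seed RNG seed.
#' @return list with `promoters` (a [PromoterSet]) and `truth` (data.frame
#'   of planted hits in [scanElements()] layout, plus an `engineered`
#'   logical column).
#' @export
simulatePromoters <- function(specs, length = 5000L,
                              motifs = defaultMotifDictionary(),
                              seed = 1L) {
  set.seed(seed)
  .checkDictionary(motifs)
  seqs <- character(base::length(specs))
  ids <- vapply(specs, `[[`, character(1), "gene_id")
  truth <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    el <- sp$elements
    nov <- if (is.null(sp$n_overlaps)) 0L else as.integer(sp$n_overlaps)
    ## resolve planted spans in promoter (positive, 1-based) coordinates
    plants <- NULL  # data.frame: start, text, truth rows
    rows <- list()
    if (!is.null(el) && nrow(el)) {
      for (k in seq_len(nrow(el))) {
        w <- if (!is.null(el$word) && !is.na(el$word[k]) &&
                 nzchar(el$word[k])) toupper(el$word[k]) else {
          pool <- motifs[[el$element_class[k]]]
          if (base::length(pool) == 1) pool else sample(pool, 1)
        }
        wlen <- nchar(w)
        start <- el$neg_start[k] + length + 1L
        if (start < 1 || start + wlen - 1L > length)
          stop("element at ", el$neg_start[k], " does not fit promoter ",
               sp$gene_id)
        text <- if (el$strand[k] == "+") w else
          as.character(reverseComplement(DNAString(w)))
        plants <- rbind(plants, data.frame(start = start, text = text,
                                           stringsAsFactors = FALSE))
        rows[[base::length(rows) + 1L]] <- data.frame(
          gene_id = sp$gene_id, element_class = el$element_class[k],
          strand = el$strand[k], neg_start = el$neg_start[k],
          neg_end = el$neg_start[k] + wlen - 1L, word = w,
          engineered = FALSE, stringsAsFactors = FALSE)
      }
    }
    if (nov > 0) {
      occ <- if (is.null(plants)) NULL else
        cbind(plants$start, plants$start + nchar(plants$text) - 1L)
      for (k in seq_len(nov)) {
        for (tries in seq_len(.MAX_REDRAWS)) {
          s <- sample(seq(2L, length - 7L), 1)
          if (is.null(occ) || all(s + 6L < occ[, 1] | s > occ[, 2])) break
          if (tries == .MAX_REDRAWS)
            stop("cannot place engineered overlap in ", sp$gene_id)
        }
        plants <- rbind(plants, data.frame(start = s, text = "ACCGACA",
                                           stringsAsFactors = FALSE))
        occ <- rbind(occ, c(s, s + 6L))
        ns <- s - (length + 1L)
        rows[[base::length(rows) + 1L]] <- data.frame(
          gene_id = rep(sp$gene_id, 2),
          element_class = c("DRE_CRT", "ARF"),
          strand = c("+", "-"),
          neg_start = c(ns, ns + 1L),
          neg_end = c(ns + 5L, ns + 6L),
          word = c("ACCGAC", "TGTCGG"),
          engineered = TRUE, stringsAsFactors = FALSE)
      }
    }
    ## collision check among planted spans
    if (!is.null(plants) && nrow(plants) > 1) {
      sp2 <- plants[order(plants$start), ]
      ends <- sp2$start + nchar(sp2$text) - 1L
      if (any(sp2$start[-1] <= ends[-nrow(sp2)]))
        stop("planted elements collide in ", sp$gene_id)
    }
    geneTruth <- if (base::length(rows)) do.call(rbind, rows) else NULL
    expected <- if (is.null(geneTruth)) character() else
      paste(geneTruth$element_class, geneTruth$strand, geneTruth$neg_start)
    bg <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    protected <- logical(length)
    if (!is.null(plants))
      for (k in seq_len(nrow(plants))) {
        s <- plants$start[k]
        e <- s + nchar(plants$text[k]) - 1L
        bg[s:e] <- strsplit(plants$text[k], "")[[1]]
        protected[s:e] <- TRUE
      }
    ## local scrub: mutate one free base inside every spurious hit until
    ## only the planted occurrences remain
    for (try in seq_len(.MAX_REDRAWS)) {
      found <- scanElements(setNames(paste(bg, collapse = ""),
                                     sp$gene_id), motifs)
      got <- paste(found$element_class, found$strand, found$neg_start)
      spurious <- which(!got %in% expected)
      if (!base::length(spurious)) break
      for (k in spurious) {
        span <- (found$neg_start[k] + length + 1L):
          (found$neg_end[k] + length + 1L)
        free <- span[!protected[span]]
        if (!base::length(free))
          stop("unscrubbable spurious element in ", sp$gene_id)
        j <- if (base::length(free) == 1) free else sample(free, 1)
        bg[j] <- sample(setdiff(c("A", "C", "G", "T"), bg[j]), 1)
      }
      if (try == .MAX_REDRAWS)
        stop("could not scrub promoter background for ", sp$gene_id)
    }
    seqs[i] <- paste(bg, collapse = "")
    found <- scanElements(setNames(seqs[i], sp$gene_id), motifs)
    got <- paste(found$element_class, found$strand, found$neg_start)
    if (!(setequal(got, expected) &&
          base::length(got) == base::length(expected)))
      stop("planted elements not exactly recoverable in ", sp$gene_id)
    if (!is.null(geneTruth)) truth[[base::length(truth) + 1L]] <- geneTruth
  }
  names(seqs) <- ids
  truthDf <- if (base::length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), element_class = character(),
               strand = character(), neg_start = integer(),
               neg_end = integer(), word = character(),
               engineered = logical())
  rownames(truthDf) <- NULL
  list(promoters = PromoterSet(seqs, anchor = "translation_start",
                               strandOfGene = "+",
                               requestedLength = length),
       truth = truthDf)
}

#' Random expression specifications
#'
#' Log2 fold changes drawn from \{0, +2, -2\} per phase; baseline TPM
#' uniform in 10-100; a small fraction of genes silent (zero TPM).
#'
#' @param n number of genes.
#' @param pSilent fraction of silent genes (default 0.1).
#' @return data.frame for [simulateExpression()].
#' @export
randomExpressionSpecs <- function(n, pSilent = 0.1) {
  data.frame(gene_id = sprintf("synthE%03d", seq_len(n)),
             base_tpm = round(runif(n, 10, 100), 2),
             lfc_dev = sample(c(0, 2, -2), n, replace = TRUE),
             lfc_ripen = sample(c(0, 2, -2), n, replace = TRUE),
             silent = runif(n) < pSilent,
             stringsAsFactors = FALSE)
}

#' Simulate a TPM matrix with planted phase trends
#'
#' Stage means follow the planted log2 fold-change trajectories: within
#' each phase, means interpolate geometrically from the phase-entry mean
#' to `2^lfc` times it; replicate values are the stage mean times
#' multiplicative lognormal noise `exp(N(0, sigma^2))`.  Silent genes are
#' zero everywhere.
#'
#' @param specs data.frame with columns `gene_id`, `base_tpm`, `lfc_dev`,
#'   `lfc_ripen`, optional `silent` (see [randomExpressionSpecs()]).
#' @param stages named list of ordered stage labels per phase (default
#'   four development stages 8-28 DPA and four ripening stages 28-53 DPA,
#'   sharing the 28 DPA boundary).
#' @param replicates biological replicates per stage (default 3).
#' @param sigma lognormal noise sd on the log scale (default 0.2).
#' @param seed RNG seed.
#' @return list with `expression` (an [ErfExpressionSet]) and `truth`
#'   (data.frame `gene_id`, `phase`, `lfc`, `direction`, `silent`).
#' @export
simulateExpression <- function(specs, stages = DEFAULT_STAGES,
                               replicates = 3L, sigma = 0.2, seed = 1L) {
  set.seed(seed)
  if (sigma < 0) stop("sigma must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (any(specs$base_tpm < 0)) stop("negative baseline TPM")
  if (is.null(specs$silent)) specs$silent <- FALSE
  allStages <- unique(unlist(stages, use.names = FALSE))
  nG <- nrow(specs)
  means <- matrix(0, nG, base::length(allStages),
                  dimnames = list(specs$gene_id, allStages))
  lfcCols <- c(development = "lfc_dev", ripening = "lfc_ripen")
  for (g in seq_len(nG)) {
    if (specs$silent[g]) next
    cur <- specs$base_tpm[g]
    means[g, stages[[1]][1]] <- cur
    for (ph in names(stages)) {
      st <- stages[[ph]]
      lfc <- specs[[lfcCols[[ph]]]][g]
      stepf <- 2^(lfc / (base::length(st) - 1))
      entry <- means[g, st[1]]
      if (entry == 0) entry <- cur
      for (s in seq(2, base::length(st))) {
        means[g, st[s]] <- entry * stepf^(s - 1)
      }
    }
  }
  lab <- rep(allStages, each = replicates)
  rep_ix <- rep(seq_len(replicates), times = base::length(allStages))
  noise <- if (sigma == 0) {
    matrix(1, nG, base::length(lab))
  } else matrix(exp(rnorm(nG * base::length(lab), 0, sigma)),
                nG, base::length(lab))
  tpm <- means[, lab, drop = FALSE] * noise
  colnames(tpm) <- paste0(lab, "_R", rep_ix)
  truth <- do.call(rbind, lapply(names(stages), function(ph) {
    lfc <- ifelse(specs$silent, 0, specs[[lfcCols[[ph]]]])
    data.frame(gene_id = specs$gene_id, phase = ph, lfc = lfc,
               direction = ifelse(lfc >= 1, "up",
                                  ifelse(lfc <= -1, "down", "flat")),
               silent = specs$silent, stringsAsFactors = FALSE)
  }))
  list(expression = ErfExpressionSet(tpm, label = lab, replicate = rep_ix),
       truth = truth)
}

#' Simulate a complete synthetic study bundle
#'
#' Generates proteins (with planted domains, residues and motifs),
#' promoters (with planted elements and engineered overlaps) and an
#' expression matrix (with planted phase trends), optionally writing all
#' of it to disk as FASTA / domtblout / TSV plus a truth JSON.
#'
#' @param nProteins,nPromoters,nGenes bundle sizes (defaults 200/50/200).
#' @param sigma expression noise (default 0.2; use 0 for noiseless truth).
#' @param replicates replicates per stage (default 3).
#' @param seed RNG seed driving every component.
#' @param dir optional output directory; created if needed.
#' @return list with `proteins`, `hits`, `promoters`, `expression`, and
#'   `truth` (a list with `residues`, `domains`, `motifs`, `elements`,
#'   `trends`).
#' @export
simulateStudy <- function(nProteins = 200L, nPromoters = 50L,
                          nGenes = 200L, sigma = 0.2, replicates = 3L,
                          seed = 1L, dir = NULL) {
  set.seed(seed)
  pspec <- randomProteinSpecs(nProteins)
  prspec <- randomPromoterSpecs(nPromoters)
  espec <- randomExpressionSpecs(nGenes)
  prot <- simulateProteins(pspec, seed = seed + 1L)
  prom <- simulatePromoters(prspec, seed = seed + 2L)
  expr <- simulateExpression(espec, replicates = replicates, sigma = sigma,
                             seed = seed + 3L)
  truth <- c(prot$truth,
             list(elements = prom$truth, trends = expr$truth))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeFasta(prot$proteins, file.path(dir, "proteins.fa"))
    writeDomtblout(prot$hits, file.path(dir, "hits.domtblout"))
    writeFasta(prom$promoters, file.path(dir, "promoters.fa"))
    writeExpressionMatrix(expr$expression, file.path(dir, "tpm.tsv"))
    write_json(lapply(truth, function(x)
      if (is.data.frame(x)) x else as.list(x)),
      file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE,
      digits = NA)
  }
  list(proteins = prot$proteins, hits = prot$hits,
       promoters = prom$promoters, expression = expr$expression,
       truth = truth)
}
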