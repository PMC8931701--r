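## End-to-end orchestration: run whichever stages the supplied inputs
## support, write TSV reports plus a JSON run summary, and record the full
## configuration (including the motif dictionary) for reproducibility.

#' Run the full ERF/DREB analysis pipeline
#'
#' Executes, for whichever inputs are provided: candidate filtering ->
#' residue extraction and subfamily classification -> binding prediction
#' -> protein-motif detection -> promoter element scan (with overlaps and
#' clusters) -> expression trends -> hormone regulatory inference.  All
#' stage outputs are written as TSV under `outdir` together with a
#' `run_summary.json` capturing the configuration, the motif dictionary
#' used, and per-stage record counts.
#'
#' @param proteins path to a protein FASTA, or an AAStringSet.
#' @param domtbl path to a `hmmsearch --domtblout` file, or a hit
#'   data.frame.
#' @param promoters path to a promoter FASTA, or a [PromoterSet] /
#'   DNAStringSet.  Alternatively supply `genome` and `gff` to extract
#'   promoters.
#' @param genome,gff genome FASTA path (or DNAStringSet) and GFF3 path,
#'   used when `promoters` is NULL.
#' @param tpm path to a TPM TSV, or an [ErfExpressionSet].
#' @param cds optional CDS FASTA path or DNAStringSet (enables codon
#'   back-analysis of positions 14/19).
#' @param outdir output directory (created if needed).
#' @param evalueMax domain E-value cutoff (default 0.001).
#' @param b3Ids protein ids carrying a B3 domain (RAV exclusion).
#' @param offset AP2 position calibration offset (default 0; see
#'   [calibrateOffset()]).
#' @param motifDict cis-element dictionary (default
#'   [defaultMotifDictionary()]).
#' @param bindingRules binding rule table (default
#'   [defaultBindingRules()]).
#' @param expressedThreshold mean-TPM expressed cutoff (default 1).
#' @param trendThreshold log2 fold-change cutoff (default 1).
#' @param eps pseudo-TPM (default 0.1).
#' @param phases stage->phase mapping for trends (default
#'   `DEFAULT_STAGES`); set NULL to skip trend/inference stages.
#' @param minOverlap,clusterK,clusterWindow promoter-scan reporting knobs.
#' @param promoterLength promoter length for extraction (default 5000).
#' @return the run summary, invisibly (a list).
#' @export
runPipeline <- function(proteins = NULL, domtbl = NULL, promoters = NULL,
                        genome = NULL, gff = NULL, tpm = NULL, cds = NULL,
                        outdir = "erfscan_out", evalueMax = 0.001,
                        b3Ids = character(), offset = 0L,
                        motifDict = defaultMotifDictionary(),
                        bindingRules = defaultBindingRules(),
                        expressedThreshold = 1, trendThreshold = 1,
                        eps = 0.1, phases = DEFAULT_STAGES,
                        minOverlap = 5L, clusterK = 4L,
                        clusterWindow = 150L, promoterLength = 5000) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(stages = list(),
                  config = list(evalue_max = evalueMax,
                                expressed_threshold = expressedThreshold,
                                trend_threshold = trendThreshold,
                                eps = eps, min_overlap = minOverlap,
                                cluster_k = clusterK,
                                cluster_window = clusterWindow,
                                motif_dictionary = motifDict))
  wtsv <- function(df, name) {
    write.table(df, file.path(outdir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  countsByGene <- NULL
  trends <- NULL

  if (!is.null(proteins) && !is.null(domtbl)) {
    prot <- stage("seq_io", {
      if (is.character(proteins)) readFasta(proteins, "protein")
      else proteins
    })
    hits <- stage("seq_io", {
      if (is.character(domtbl)) readDomtblout(domtbl) else domtbl
    })
    part <- stage("seq_io",
                  filterCandidates(hits, prot, evalueMax, b3Ids))
    summary$stages$filter <- as.list(part$counts)
    best <- selectBestHits(part$hits)
    kr <- stage("ap2_classify", extractKeyResidues(prot, best, offset))
    calls <- stage("ap2_classify",
                   suppressWarnings(classifySubfamily(kr)))
    report <- merge(kr, calls[, c("protein_id", "subfamily", "rule_fired")],
                    by = "protein_id")
    p14 <- residueProperties(report$pos14)
    report$pos14_character <- p14$character
    report$pos14_polarity <- p14$polarity
    if (!is.null(cds)) {
      cdsSet <- stage("seq_io", {
        if (is.character(cds)) readFasta(cds, "dna") else cds
      })
      report$codon14 <- vapply(seq_len(nrow(report)), function(i) {
        id <- report$protein_id[i]
        if (!id %in% names(cdsSet)) return(NA_character_)
        h <- best[best$protein_id == id, ]
        codonAt(cdsSet[[id]], prot[[id]],
                h$ali_from + (14L + offset - h$hmm_from))
      }, character(1))
    }
    wtsv(report, "subfamily_calls")
    wtsv(summarizeFamily(calls), "family_summary")
    summary$stages$classify <-
      list(n = nrow(calls),
           dreb = sum(calls$subfamily == "DREB"),
           erf = sum(calls$subfamily == "ERF"),
           unclassified = sum(calls$subfamily == "unclassified"))

    bind <- stage("binding_rules", predictBinding(kr, bindingRules))
    wtsv(bind, "binding_predictions")
    summary$stages$binding <-
      as.list(table(bind$category))

    mot <- stage("protein_motifs", findProteinMotifs(prot[part$single_domain]))
    rep_calls <- stage("protein_motifs",
                       classifyRepressors(mot, part$single_domain))
    wtsv(mot, "protein_motifs")
    wtsv(rep_calls, "repressor_calls")
    summary$stages$motifs <-
      list(n_hits = nrow(mot),
           ear_containing = sum(rep_calls$status != "none"))
  } else summary$stages$classify <- "skipped (no proteins/domtbl)"

  if (is.null(promoters) && !is.null(genome) && !is.null(gff)) {
    promoters <- stage("seq_io", {
      gn <- if (is.character(genome)) readFasta(genome, "dna") else genome
      extractPromoters(gn, gff, length = promoterLength)
    })
  }
  if (!is.null(promoters)) {
    prom <- stage("seq_io", {
      if (is.character(promoters)) readFasta(promoters, "dna")
      else promoters
    })
    eh <- stage("promoter_elements", scanElements(prom, motifDict))
    ov <- stage("promoter_elements", findElementOverlaps(eh, minOverlap))
    cl <- stage("promoter_elements",
                findElementClusters(eh, clusterK, clusterWindow))
    countsByGene <- countElements(eh, geneIds = names(prom))
    wtsv(eh, "element_hits")
    wtsv(ov, "element_overlaps")
    wtsv(cl, "element_clusters")
    wtsv(countsByGene, "element_counts")
    summary$stages$promoters <-
      list(n_hits = nrow(eh), n_overlaps = nrow(ov),
           n_clusters = nrow(cl))
  } else summary$stages$promoters <- "skipped (no promoters)"

  if (!is.null(tpm)) {
    expr <- stage("seq_io", {
      if (is.character(tpm)) readExpressionMatrix(tpm) else tpm
    })
    cnt <- expressedCounts(expr, threshold = expressedThreshold)
    wtsv(data.frame(label = names(cnt), expressed = as.integer(cnt)),
         "expressed_counts")
    summary$stages$expression <- list(n_genes = nrow(expr),
                                      n_samples = ncol(expr))
    if (!is.null(phases) &&
        all(unlist(phases) %in% sampleLabels(expr))) {
      trends <- stage("expression_trends",
                      phaseTrend(expr, phases, trendThreshold, eps))
      wtsv(trends, "trend_calls")
      summary$stages$trends <- list(n = nrow(trends))
    }
  } else summary$stages$expression <- "skipped (no tpm)"

  if (!is.null(trends) && !is.null(countsByGene)) {
    reg <- stage("regulatory_inference",
                 inferRegulationTable(trends, countsByGene))
    wtsv(reg, "regulatory_calls")
    summary$stages$inference <- as.list(table(reg$mode))
  } else summary$stages$inference <-
    "skipped (needs both trends and promoter counts)"

  write_json(summary, file.path(outdir, "run_summary.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
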