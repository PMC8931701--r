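## Hormone regulatory inference: combine the development-phase and
## ripening-phase expression trends with promoter element counts into
## direct/indirect IAA and ET calls.
##
## Precedence: the trend decides first.  A flat trend yields no call
## regardless of how many elements the promoter carries; a non-flat trend
## is "direct" when at least one relevant element is present (ARF for the
## auxin/IAA axis; DRE/CRT or GCC box, unweighted, for the ethylene/ET
## axis) and "indirect" otherwise.

.MODE_TABLE <- c(up.direct = "direct_induction",
                 up.indirect = "indirect_induction",
                 down.direct = "direct_repression",
                 down.indirect = "indirect_repression")

.inferOne <- function(trend, nElements) {
  if (trend == "flat") return("none")
  .MODE_TABLE[[paste(trend, if (nElements >= 1) "direct" else "indirect",
                     sep = ".")]]
}

#' Infer IAA and ET regulatory modes for one gene
#'
#' The IAA call combines the development-phase trend with the ARF-site
#' count; the ET call combines the ripening-phase trend with the combined
#' DRE/CRT + GCC-box count.  Four-way logic per hormone: up with >= 1
#' relevant element is direct induction, up without is indirect induction,
#' and symmetrically for down; a flat trend gives `none`.  Deterministic
#' and total over the evidence domain.
#'
#' @param trendDev development-phase direction: `"up"`, `"down"`, `"flat"`.
#' @param trendRipen ripening-phase direction.
#' @param counts named numeric vector with elements `ARF`, `DRE_CRT`,
#'   `GCC`.
#' @param geneId optional gene id to record.
#' @return data.frame with two rows (hormones IAA and ET) and columns
#'   `gene_id`, `hormone`, `mode`, `trend`, `n_elements`.
#' @export
inferRegulation <- function(trendDev, trendRipen, counts,
                            geneId = NA_character_) {
  dirs <- c("up", "down", "flat")
  if (is.na(trendDev) || is.na(trendRipen) ||
      !trendDev %in% dirs || !trendRipen %in% dirs)
    stop("trend directions must be 'up', 'down' or 'flat'")
  need <- setdiff(ELEMENT_CLASSES, names(counts))
  if (length(need))
    stop("element count(s) missing: ", paste(need, collapse = ", "))
  nIaa <- as.numeric(counts[["ARF"]])
  nEt <- as.numeric(counts[["DRE_CRT"]]) + as.numeric(counts[["GCC"]])
  data.frame(gene_id = geneId,
             hormone = c("IAA", "ET"),
             mode = c(.inferOne(trendDev, nIaa), .inferOne(trendRipen, nEt)),
             trend = c(trendDev, trendRipen),
             n_elements = c(nIaa, nEt),
             stringsAsFactors = FALSE)
}

#' Regulatory inference across a gene table
#'
#' Joins per-gene trend calls (from [phaseTrend()]) with per-gene element
#' counts (from [countElements()]) and applies [inferRegulation()] to each
#' gene.
#'
#' @param trends data.frame from [phaseTrend()] containing both phases.
#' @param counts data.frame from [countElements()].
#' @param devPhase,ripenPhase the phase names to use for the IAA and ET
#'   axes (defaults `"development"`, `"ripening"`).
#' @return data.frame, two rows per gene.
#' @export
inferRegulationTable <- function(trends, counts,
                                 devPhase = "development",
                                 ripenPhase = "ripening") {
  genes <- intersect(unique(trends$gene_id), counts$gene_id)
  out <- lapply(genes, function(g) {
    td <- trends$direction[trends$gene_id == g & trends$phase == devPhase]
    tr <- trends$direction[trends$gene_id == g & trends$phase == ripenPhase]
    if (!length(td) || !length(tr))
      stop("missing phase trend for gene ", g)
    cnt <- counts[counts$gene_id == g, ELEMENT_CLASSES]
    inferRegulation(td[1], tr[1], unlist(cnt), geneId = g)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- inferRegulation("flat", "flat",
                           c(ARF = 0, DRE_CRT = 0, GCC = 0))[0, ]
  rownames(res) <- NULL
  res
}
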