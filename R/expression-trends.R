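## Expression-side computations on TPM matrices: expressed-gene counts per
## organ, EAR-set TPM ratios, endpoint phase-trend classification, and
## delta-delta-Ct relative expression for qRT-PCR tables.

#' Count expressed genes per sample label
#'
#' A gene counts as expressed in an organ/stage when its replicate-mean
#' TPM there is at least `threshold` (default 1 TPM, the conventional
#' expressed/silent line).
#'
#' @param x an [ErfExpressionSet].
#' @param geneSet character vector of gene ids (subset of `rownames(x)`).
#' @param threshold mean-TPM threshold (default 1).
#' @return named integer vector, one count per label.
#' @export
expressedCounts <- function(x, geneSet = rownames(x), threshold = 1) {
  unknown <- setdiff(geneSet, rownames(x))
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  m <- labelMeans(x)[geneSet, , drop = FALSE]
  apply(m >= threshold, 2, sum)
}

#' EAR-set share of total TPM per sample label
#'
#' 100 x (summed replicate-mean TPM of the EAR-motif gene set) / (summed
#' replicate-mean TPM of the full gene set), per organ/stage.  A label
#' whose full-set total is zero yields `NaN` (undefined).
#'
#' @param x an [ErfExpressionSet].
#' @param earSet gene ids of the EAR-motif-containing set.
#' @param allSet gene ids of the full family set (must contain `earSet`).
#' @return named numeric vector of percentages in `[0, 100]`.
#' @export
earTpmRatio <- function(x, earSet, allSet = rownames(x)) {
  if (!length(allSet)) stop("empty reference gene set")
  unknown <- setdiff(allSet, rownames(x))
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  if (length(setdiff(earSet, allSet)))
    stop("earSet must be a subset of allSet")
  m <- labelMeans(x)
  num <- colSums(m[earSet, , drop = FALSE])
  den <- colSums(m[allSet, , drop = FALSE])
  100 * num / den
}

#' Classify expression trends within developmental phases
#'
#' For each gene and phase, computes the endpoint log2 fold change
#' `log2((last + eps) / (first + eps))` between the first and last stage
#' means of the phase (stages in the given order), and calls the direction
#' `up` when the log2 fold change is at least `threshold`, `down` when at
#' most `-threshold`, else `flat`.  A Spearman correlation of stage means
#' against stage rank is reported per phase as a monotonicity diagnostic
#' (it does not gate the call).
#'
#' @param x an [ErfExpressionSet] whose labels are stages, or a numeric
#'   genes-x-stages matrix of stage means.
#' @param phases named list mapping phase name to the ordered stage labels
#'   it spans (at least 2 per phase), e.g.
#'   `list(development = c("8DPA", "28DPA"), ripening = c("28DPA", "53DPA"))`.
#' @param threshold absolute log2 fold-change cutoff (default 1).
#' @param eps pseudo-TPM guarding zero denominators (default 0.1).
#' @return data.frame with columns `gene_id`, `phase`, `log2fc`,
#'   `direction`, `rho`.
#' @export
phaseTrend <- function(x, phases, threshold = 1, eps = 0.1) {
  m <- if (methods::is(x, "ErfExpressionSet")) labelMeans(x) else as.matrix(x)
  if (!length(phases) || is.null(names(phases)))
    stop("phases must be a named list of stage-label vectors")
  short <- lengths(phases) < 2
  if (any(short))
    stop("phase(s) with < 2 stages: ",
         paste(names(phases)[short], collapse = ", "))
  out <- list()
  for (ph in names(phases)) {
    stages <- as.character(phases[[ph]])
    missing <- setdiff(stages, colnames(m))
    if (length(missing))
      stop("stage(s) absent from matrix: ", paste(missing, collapse = ", "))
    sub <- m[, stages, drop = FALSE]
    lfc <- log2((sub[, ncol(sub)] + eps) / (sub[, 1] + eps))
    rho <- apply(sub, 1, function(v)
      if (stats::sd(v) == 0) 0 else
        suppressWarnings(cor(v, seq_along(v), method = "spearman")))
    out[[ph]] <- data.frame(
      gene_id = rownames(m), phase = ph, log2fc = unname(lfc),
      direction = ifelse(lfc >= threshold, "up",
                         ifelse(lfc <= -threshold, "down", "flat")),
      rho = unname(rho), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative expression from qRT-PCR Ct values (delta-delta-Ct)
#'
#' For each target gene and sample: `dCt = Ct_target - Ct_reference`;
#' `fold = efficiency^-(dCt_sample - dCt_calibrator)`.  The calibrator
#' sample's fold is 1 by construction.  Technical replicates (multiple Ct
#' rows per gene/sample) are averaged first.  Amplification efficiency
#' defaults to 2 (perfect doubling per cycle).
#'
#' @param ct data.frame with columns `gene_id`, `sample`, `ct` (finite
#'   numeric).
#' @param referenceGene id of the internal-control gene; must have a Ct in
#'   every sample.
#' @param calibratorSample sample name used as calibrator.
#' @param efficiency amplification efficiency (default 2).
#' @return data.frame with columns `gene_id`, `sample`, `fold`.
#' @export
relativeExpression <- function(ct, referenceGene, calibratorSample,
                               efficiency = 2) {
  stopifnot(all(c("gene_id", "sample", "ct") %in% names(ct)))
  if (anyNA(ct$ct) || any(!is.finite(ct$ct))) stop("non-finite Ct value")
  mean_ct <- stats::aggregate(ct ~ gene_id + sample, data = ct, FUN = mean)
  samples <- unique(ct$sample)
  if (!calibratorSample %in% samples)
    stop("calibrator sample not in Ct table: ", calibratorSample)
  ref <- mean_ct[mean_ct$gene_id == referenceGene, ]
  if (length(setdiff(samples, ref$sample)))
    stop("reference gene ", referenceGene, " missing Ct in sample(s): ",
         paste(setdiff(samples, ref$sample), collapse = ", "))
  refCt <- setNames(ref$ct, ref$sample)
  tgt <- mean_ct[mean_ct$gene_id != referenceGene, , drop = FALSE]
  tgt$dct <- tgt$ct - refCt[tgt$sample]
  out <- list()
  for (g in unique(tgt$gene_id)) {
    rows <- tgt[tgt$gene_id == g, , drop = FALSE]
    cal <- rows$dct[rows$sample == calibratorSample]
    if (!length(cal))
      stop("gene ", g, " has no Ct in calibrator sample ", calibratorSample)
    out[[g]] <- data.frame(gene_id = g, sample = rows$sample,
                           fold = efficiency^-(rows$dct - cal),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
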