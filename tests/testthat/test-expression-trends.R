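mkExpr <- function(m, labels, reps = NULL) {
  if (is.null(reps)) reps <- rep(1L, length(labels))
  ErfExpressionSet(m, label = labels, replicate = reps)
}

test_that("expressed-gene counting applies the mean-TPM threshold", {
  m <- matrix(c(5, 0.2, 1.0), 3, 1,
              dimnames = list(c("g1", "g2", "g3"), "leaf_R1"))
  x <- mkExpr(m, "leaf")
  expect_equal(unname(expressedCounts(x, threshold = 1)["leaf"]), 2L)
  expect_equal(unname(expressedCounts(x, threshold = 0)["leaf"]), 3L)
  expect_error(expressedCounts(x, geneSet = "nope"), "unknown gene")
  ## replicate means, not single samples, decide
  m2 <- matrix(c(0.5, 2.0), 1, 2, dimnames = list("g1", NULL))
  x2 <- mkExpr(m2, c("leaf", "leaf"), 1:2)
  expect_equal(unname(expressedCounts(x2, threshold = 1)["leaf"]), 1L)
})

test_that("expressed counts match planted expressed/silent truth", {
  set.seed(61)
  specs <- randomExpressionSpecs(100)
  sim <- simulateExpression(specs, sigma = 0, seed = 62)
  cnt <- expressedCounts(sim$expression, threshold = 1)
  ## at the baseline stage, expressed genes sit at their >= 10 TPM
  ## baseline and silent genes at zero (later stages may drop trending
  ## genes below threshold, so only the baseline is truth-determined)
  expect_equal(unname(cnt["8DPA"]), sum(!specs$silent))
  ## silent genes are never counted anywhere
  silent <- specs$gene_id[specs$silent]
  if (length(silent))
    expect_true(all(expressedCounts(sim$expression, silent,
                                    threshold = 1e-9) == 0))
})

test_that("EAR TPM ratio is a percentage with complement closure", {
  m <- matrix(c(60, 40, 30, 70), 2, 2,
              dimnames = list(c("ear1", "oth1"), c("a_R1", "b_R1")))
  x <- mkExpr(m, c("a", "b"))
  r <- earTpmRatio(x, "ear1")
  expect_equal(unname(r), c(60, 30))
  expect_equal(unname(earTpmRatio(x, c("ear1", "oth1"))), c(100, 100))
  ## complement sums to 100 within tolerance
  expect_equal(unname(r + earTpmRatio(x, "oth1")), c(100, 100),
               tolerance = 1e-9)
  expect_true(all(r >= 0 & r <= 100))
  expect_error(earTpmRatio(x, "ear1", allSet = character()), "empty")
  expect_error(earTpmRatio(x, "zz"), "subset|unknown")
})

test_that("phase trends use endpoint log2 fold change with pseudo-TPM", {
  m <- matrix(c(2, 4, 7, 10,   5, 5.1, 5.0, 5.2), 2, 4, byrow = TRUE,
              dimnames = list(c("up1", "flat1"),
                              c("s1_R1", "s2_R1", "s3_R1", "s4_R1")))
  x <- mkExpr(m, c("s1", "s2", "s3", "s4"))
  tr <- phaseTrend(x, list(development = c("s1", "s2", "s3", "s4")))
  expect_equal(tr$log2fc[tr$gene_id == "up1"],
               log2(10.1 / 2.1), tolerance = 1e-12)
  expect_equal(tr$direction, c("up", "flat"))
  ## monotonicity diagnostic
  expect_equal(tr$rho[tr$gene_id == "up1"], 1)
  ## scale invariance of the direction (eps scaled with the data)
  tr10 <- phaseTrend(x, list(development = c("s1", "s2", "s3", "s4")),
                     eps = 1)
  m10 <- mkExpr(m * 10, c("s1", "s2", "s3", "s4"))
  tr10b <- phaseTrend(m10, list(development = c("s1", "s2", "s3", "s4")),
                      eps = 10)
  expect_equal(tr10$log2fc, tr10b$log2fc)
  expect_error(phaseTrend(x, list(dev = "s1")), "< 2 stages")
})

test_that("trend direction is invariant under replicate relabeling", {
  set.seed(63)
  sim <- simulateExpression(randomExpressionSpecs(30), sigma = 0.2,
                            seed = 64)
  x <- sim$expression
  tr1 <- phaseTrend(x, DEFAULT_STAGES)
  perm <- sample(ncol(x))
  x2 <- ErfExpressionSet(SummarizedExperiment::assay(x, "tpm")[, perm],
                         label = sampleLabels(x)[perm],
                         replicate = SummarizedExperiment::colData(x)$replicate[perm])
  tr2 <- phaseTrend(x2, DEFAULT_STAGES)
  expect_equal(tr1$direction, tr2$direction)
  expect_equal(tr1$log2fc, tr2$log2fc)
})

test_that("trend recovery meets the planted-truth targets", {
  ## noiseless: directions match planted truth exactly
  set.seed(65)
  specs <- randomExpressionSpecs(60)
  sim0 <- simulateExpression(specs, sigma = 0, seed = 66)
  tr0 <- phaseTrend(sim0$expression, DEFAULT_STAGES)
  mg0 <- merge(tr0, sim0$truth, by = c("gene_id", "phase"))
  expect_equal(mean(mg0$direction.x == mg0$direction.y), 1)
  ## planted log2fc of 2 is recovered up to the eps adjustment
  up <- mg0[mg0$lfc == 2 & !mg0$silent, ]
  expect_true(all(abs(up$log2fc.x - 2) < 0.05))

  ## noisy study conditions: sigma 0.2, 3 replicates, lfc in {0, +-2}
  sim1 <- simulateExpression(randomExpressionSpecs(200), sigma = 0.2,
                             replicates = 3, seed = 67)
  tr1 <- phaseTrend(sim1$expression, DEFAULT_STAGES)
  mg1 <- merge(tr1, sim1$truth, by = c("gene_id", "phase"))
  expect_gte(mean(mg1$direction.x == mg1$direction.y), 0.95)
})

test_that("delta-delta-Ct folds follow the doubling model", {
  ct <- expand.grid(gene_id = c("target", "actin"),
                    sample = c("MG", "BR"), stringsAsFactors = FALSE)
  ct$ct <- 20
  expect_equal(relativeExpression(ct, "actin", "MG")$fold, c(1, 1))

  ## target one cycle lower than calibrator, reference unchanged -> 2x
  ct2 <- ct
  ct2$ct[ct2$gene_id == "target" & ct2$sample == "BR"] <- 19
  r <- relativeExpression(ct2, "actin", "MG")
  expect_equal(r$fold[r$sample == "BR"], 2)
  expect_equal(r$fold[r$sample == "MG"], 1)

  ## random tables match a direct formula oracle
  set.seed(68)
  tab <- expand.grid(gene_id = c("g1", "g2", "ref"),
                     sample = paste0("s", 1:4), stringsAsFactors = FALSE)
  tab$ct <- runif(nrow(tab), 18, 30)
  got <- relativeExpression(tab, "ref", "s1")
  for (g in c("g1", "g2")) for (s in paste0("s", 1:4)) {
    dct <- function(gg, ss) tab$ct[tab$gene_id == gg & tab$sample == ss]
    want <- 2^-((dct(g, s) - dct("ref", s)) - (dct(g, "s1") - dct("ref", "s1")))
    expect_equal(got$fold[got$gene_id == g & got$sample == s], want)
  }
  ## missing reference Ct
  expect_error(relativeExpression(tab[tab$gene_id != "ref", ], "ref", "s1"),
               "reference gene")
})
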