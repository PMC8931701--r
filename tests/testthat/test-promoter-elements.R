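test_that("element scanning reports negative coordinates on both strands", {
  ## planted GCC box: promoter positions 4-9 of a 12-bp promoter
  h <- scanElements(c(g = "AAAGCCGCCAAA"),
                    motifs = list(GCC = "GCCGCC"))
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "+")
  expect_equal(h$neg_start, -9)
  expect_equal(h$neg_end, -4)

  ## 9-bp toy: DRE on + strand and an ARF word visible as its reverse
  ## complement (CCGACA) on the - strand, overlapping by 5 bp
  h <- scanElements(c(g = "TACCGACAT"),
                    motifs = list(DRE_CRT = c("ACCGAC", "GCCGAC"),
                                  ARF = c("TGTCTC", "TGTCGG")))
  expect_equal(nrow(h), 2)
  dre <- h[h$element_class == "DRE_CRT", ]
  arf <- h[h$element_class == "ARF", ]
  expect_equal(c(dre$strand, dre$neg_start, dre$neg_end),
               c("+", -8, -3))
  expect_equal(c(arf$strand, arf$neg_start, arf$neg_end),
               c("-", -7, -2))

  expect_error(scanElements(c(g = "ACGT"), motifs = list()), "empty")
})

test_that("scanner matches the brute-force oracle on random sequences", {
  set.seed(51)
  dict <- defaultMotifDictionary()
  for (i in 1:100) {
    n <- sample(200:5000, 1)
    s <- randomDnaSeq(n)
    got <- scanElements(setNames(s, "g"), dict)
    want <- naiveElementScan(s, dict)
    if (is.null(want)) {
      expect_equal(nrow(got), 0, info = i)
    } else {
      key <- function(d) sort(paste(d$element_class, d$strand,
                                    d$neg_start, d$word))
      expect_equal(key(got), key(want), info = i)
    }
  }
})

test_that("scanning the reverse complement mirrors coordinates and strands", {
  set.seed(52)
  s <- paste0(randomDnaSeq(100), "ACCGAC", randomDnaSeq(50), "TGTCTC",
              randomDnaSeq(100))
  L <- nchar(s)
  f <- scanElements(setNames(s, "g"))
  r <- scanElements(setNames(rcomp(s), "g"))
  expect_equal(nrow(f), nrow(r))
  ## a + hit at [ns, ne] maps to a - hit at [-(L+1)-ne, -(L+1)-ns]
  keyf <- sort(paste(f$element_class,
                     ifelse(f$strand == "+", "-", "+"),
                     -(L + 1) - f$neg_end, -(L + 1) - f$neg_start))
  keyr <- sort(paste(r$element_class, r$strand, r$neg_start, r$neg_end))
  expect_equal(keyr, keyf)
})

test_that("overlap detection reports cross-class span intersections", {
  h <- scanElements(c(g = "TACCGACAT"),
                    motifs = list(DRE_CRT = "ACCGAC", ARF = "TGTCGG"))
  ov <- findElementOverlaps(h, minOverlap = 5)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$overlap_bp, 5)
  ## raising the threshold excludes the pair
  expect_equal(nrow(findElementOverlaps(h, minOverlap = 6)), 0)
  ## same-class pairs are never reported
  h2 <- data.frame(gene_id = "g", element_class = c("ARF", "ARF"),
                   strand = "+", neg_start = c(-20, -18),
                   neg_end = c(-15, -13), word = "TGTCTC")
  expect_equal(nrow(findElementOverlaps(h2)), 0)
  ## disjoint hits
  h3 <- data.frame(gene_id = "g", element_class = c("ARF", "GCC"),
                   strand = "+", neg_start = c(-50, -20),
                   neg_end = c(-45, -15), word = "x")
  expect_equal(nrow(findElementOverlaps(h3)), 0)
  ## identical spans overlap by the word length
  h4 <- data.frame(gene_id = "g", element_class = c("ARF", "DRE_CRT"),
                   strand = c("+", "-"), neg_start = -20, neg_end = -15,
                   word = "x")
  expect_equal(findElementOverlaps(h4, minOverlap = 6)$overlap_bp, 6)
})

test_that("cluster detection finds dense same-class runs", {
  mkhits <- function(negs, cls = "ARF")
    data.frame(gene_id = "g", element_class = cls, strand = "+",
               neg_start = negs, neg_end = negs + 5, word = "TGTCTC")
  ## 4 sites within 120 bp
  cl <- findElementClusters(mkhits(c(-4363, -4330, -4290, -4249)),
                            k = 4, window = 150)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$count, 4)
  expect_equal(cl$neg_start, -4363)
  expect_equal(cl$neg_end, -4244)
  ## 3 sites spread over 2 kb: no cluster
  expect_equal(nrow(findElementClusters(mkhits(c(-3000, -2000, -1000)),
                                        k = 3, window = 150)), 0)
})

test_that("greedy clusters agree with exhaustive search on small inputs", {
  ## oracle: all maximal sets of >= k same-class sites with span <= window
  ## are contiguous in sorted order; enumerate all contiguous runs
  bruteClusters <- function(negs, k, window, wlen = 6) {
    negs <- sort(negs)
    ends <- negs + wlen - 1
    res <- NULL
    taken <- rep(FALSE, length(negs))
    i <- 1
    while (i <= length(negs)) {
      best_j <- NA
      for (j in seq(i, length(negs)))
        if (max(ends[i:j]) - negs[i] + 1 <= window) best_j <- j
      if (!is.na(best_j) && best_j - i + 1 >= k) {
        res <- rbind(res, data.frame(neg_start = negs[i],
                                     neg_end = max(ends[i:best_j]),
                                     count = best_j - i + 1))
        i <- best_j + 1
      } else i <- i + 1
    }
    res
  }
  set.seed(53)
  for (trial in 1:50) {
    n <- sample(2:10, 1)
    negs <- sort(sample(seq(-4900, -10, by = 9), n))
    hits <- data.frame(gene_id = "g", element_class = "ARF", strand = "+",
                       neg_start = negs, neg_end = negs + 5, word = "w")
    got <- findElementClusters(hits, k = 3, window = 200)
    want <- bruteClusters(negs, k = 3, window = 200)
    if (is.null(want)) {
      expect_equal(nrow(got), 0, info = trial)
    } else {
      expect_equal(got[, c("neg_start", "neg_end", "count")], want,
                   ignore_attr = TRUE, info = trial)
    }
  }
})

test_that("element counting deduplicates palindromic double hits", {
  ## palindromic word: hits the same span on both strands, counts once
  h <- scanElements(c(g = "AAAGGCGCCAAA"),
                    motifs = list(GCC = "GGCGCC"))
  expect_equal(nrow(h), 2)  # both strands reported
  cnt <- countElements(h, classes = "GCC")
  expect_equal(cnt$GCC, 1)  # but one distinct site

  h2 <- scanElements(c(g = "TTGTCTCAATGTCTCAAGCCGCCTT"),
                     motifs = defaultMotifDictionary())
  cnt2 <- countElements(h2)
  expect_equal(cnt2$ARF, 2)
  expect_equal(cnt2$GCC, 1)
  expect_equal(cnt2$DRE_CRT, 0)
  ## conservation: totals equal distinct spans
  expect_equal(sum(cnt2[, c("ARF", "DRE_CRT", "GCC")]),
               nrow(unique(h2[, c("element_class", "neg_start", "neg_end")])))
  empty <- countElements(h2[0, ], geneIds = "g")
  expect_equal(unname(unlist(empty[, -1])), c(0L, 0L, 0L))
})

test_that("planted elements are recovered with exact coordinates", {
  specs <- list(
    list(gene_id = "g1",
         elements = data.frame(element_class = "GCC", strand = "+",
                               neg_start = -100),
         n_overlaps = 0L),
    list(gene_id = "g2", elements = NULL, n_overlaps = 1L),
    list(gene_id = "g3", elements = NULL, n_overlaps = 0L))
  sim <- simulatePromoters(specs, length = 600, seed = 54)
  hits <- scanElements(sim$promoters)
  ## g1: exactly one GCC at -100..-95
  g1 <- hits[hits$gene_id == "g1", ]
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$neg_start, g1$neg_end), c(-100, -95))
  ## g2: engineered ARF/DRE pair overlapping by exactly 5 bp
  ov <- findElementOverlaps(hits[hits$gene_id == "g2", ], minOverlap = 5)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$overlap_bp, 5)
  ## g3: clean background, zero hits
  expect_equal(nrow(hits[hits$gene_id == "g3", ]), 0)
})
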