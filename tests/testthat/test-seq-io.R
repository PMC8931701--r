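test_that("FASTA reading preserves order, upper-cases, and validates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "mkv", ">b desc text", "MKLV"), f)
  x <- readFasta(f, "protein")
  expect_equal(names(x), c("a", "b"))
  expect_equal(as.character(x), c(a = "MKV", b = "MKLV"))

  writeLines(c(">a", "MKV", ">a", "MML"), f)
  expect_error(readFasta(f, "protein"), "duplicate.*a")

  writeLines(c(">a", "MKZV"), f)
  expect_error(readFasta(f, "protein"), "non-standard")

  writeLines(c(">a", "ACGTN", ">b", "acgt"), f)
  expect_equal(as.character(readFasta(f, "dna")),
               c(a = "ACGTN", b = "ACGT"))
})

test_that("FASTA round-trip reproduces ids and sequences exactly", {
  set.seed(11)
  seqs <- setNames(vapply(1:5, function(i) randomProteinSeq(50),
                          character(1)),
                   paste0("p", 1:5))
  f <- withr::local_tempfile(fileext = ".fa")
  writeFasta(Biostrings::AAStringSet(seqs), f)
  back <- readFasta(f, "protein")
  expect_identical(as.character(back), seqs)
})

test_that("domtblout parsing maps ali/hmm columns and E-value", {
  f <- withr::local_tempfile(fileext = ".domtblout")
  row <- paste("prot1 - 300 AP2 PF00847.2 58 1e-25 90.1 0.1 1 1",
               "2e-22 1e-20 85.3 0.1 1 58 5 62 4 63 0.98 -")
  writeLines(c("# comment line", row), f)
  h <- readDomtblout(f)
  expect_equal(nrow(h), 1)
  expect_equal(h$ali_from, 5)
  expect_equal(h$ali_to, 62)
  expect_equal(h$hmm_from, 1)
  expect_equal(h$hmm_to, 58)
  expect_equal(h$evalue, 1e-20)

  writeLines(c("# only", "# comments"), f)
  expect_equal(nrow(readDomtblout(f)), 0)

  writeLines(c(row, row), f)
  expect_equal(readDomtblout(f)$protein_id, c("prot1", "prot1"))

  writeLines("prot1 broken row", f)
  expect_error(readDomtblout(f), "line 1")
})

test_that("domtblout writer round-trips through the reader", {
  hits <- data.frame(protein_id = c("a", "b"),
                     ali_from = c(10L, 3L), ali_to = c(67L, 60L),
                     hmm_from = c(1L, 2L), hmm_to = c(58L, 58L),
                     evalue = c(1e-30, 2e-10))
  f <- withr::local_tempfile()
  writeDomtblout(hits, f)
  expect_equal(readDomtblout(f), hits)
})

test_that("candidate filtering partitions by domain count and B3 status", {
  mk <- function(id, n, e = 1e-10)
    data.frame(protein_id = id, ali_from = seq(1, by = 70, length.out = n),
               ali_to = seq(58, by = 70, length.out = n),
               hmm_from = 1L, hmm_to = 58L, evalue = e)
  hits <- rbind(mk("m1", 2), mk("s1", 1), mk("s2", 1), mk("s3", 1),
                mk("rav1", 1), mk("weak", 1, e = 0.5))
  part <- filterCandidates(hits, evalueMax = 0.001, b3Ids = "rav1")
  expect_equal(unname(part$counts),
               c(1L, 3L, 1L))
  expect_setequal(part$single_domain, c("s1", "s2", "s3"))
  expect_equal(part$rav_excluded, "rav1")
  ## partition property: groups cover exactly the surviving proteins
  surviving <- unique(hits$protein_id[hits$evalue <= 0.001])
  expect_setequal(c(part$multi_domain, part$single_domain,
                    part$rav_excluded), surviving)

  all_weak <- filterCandidates(mk("x", 1, e = 0.5))
  expect_equal(sum(all_weak$counts), 0L)
})

test_that("best-hit selection prefers lowest E-value then leftmost", {
  hits <- data.frame(protein_id = c("a", "a", "b", "b"),
                     ali_from = c(5L, 100L, 50L, 7L),
                     ali_to = c(62L, 157L, 107L, 64L),
                     hmm_from = 1L, hmm_to = 58L,
                     evalue = c(1e-10, 1e-30, 1e-5, 1e-5))
  best <- selectBestHits(hits)
  expect_equal(best$ali_from[best$protein_id == "a"], 100L)
  expect_equal(best$ali_from[best$protein_id == "b"], 7L)
})

test_that("promoter extraction slices upstream of the anchor per strand", {
  chr <- paste(rep("A", 20), collapse = "")
  substr(chr, 6, 10) <- "CGTAC"
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(11, 5), c(15, 10)),
                               strand = c("+", "-"),
                               gene_id = c("gplus", "gminus"))
  p <- extractPromoters(genome, gr, length = 5)
  ## + gene at 11: promoter = bases 6..10
  expect_equal(as.character(p[["gplus"]]), "CGTAC")
  ## - gene ending at 10: promoter = revcomp of bases 11..15
  expect_equal(as.character(p[["gminus"]]), rcomp(substr(chr, 11, 15)))
  expect_s4_class(p, "PromoterSet")
  expect_equal(unique(S4Vectors::mcols(p)$requested_length), 5L)
})

test_that("promoter extraction truncates at chromosome edges", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGTACGTACGT"))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3, 10),
                               strand = "+", gene_id = "edge")
  expect_warning(p <- extractPromoters(genome, gr, length = 5),
                 "truncated")
  expect_equal(as.character(p[["edge"]]), "AC")
  expect_error(extractPromoters(genome, gr, length = 5, geneIds = "nope"),
               "absent")
  expect_error(extractPromoters(genome, gr, length = 0), "positive")
})

test_that("promoter extraction is strand-symmetric", {
  ## extracting from a genome and from its reverse complement (with
  ## mirrored annotation) gives identical promoter sequences
  set.seed(21)
  chr <- randomDnaSeq(300)
  genome_f <- Biostrings::DNAStringSet(c(c1 = chr))
  genome_r <- Biostrings::DNAStringSet(c(c1 = rcomp(chr)))
  anchor <- 151L  # + gene starts here
  gr_f <- GenomicRanges::GRanges("c1", IRanges::IRanges(anchor, 200),
                                 strand = "+", gene_id = "g")
  ## mirrored gene on the reverse-complemented chromosome
  gr_r <- GenomicRanges::GRanges("c1",
                                 IRanges::IRanges(300 - 200 + 1,
                                                  300 - anchor + 1),
                                 strand = "-", gene_id = "g")
  pf <- extractPromoters(genome_f, gr_f, length = 50)
  pr <- extractPromoters(genome_r, gr_r, length = 50)
  expect_equal(as.character(pf[["g"]]), as.character(pr[["g"]]))
})

test_that("expression matrix reading parses replicate structure", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tleaf_R1\tleaf_R2\tleaf_R3\troot_R1\troot_R2\troot_R3",
               "g1\t1\t2\t3\t4\t5\t6",
               "g2\t0\t0\t0\t1\t1\t1"), f)
  x <- readExpressionMatrix(f)
  expect_s4_class(x, "ErfExpressionSet")
  expect_equal(sort(unique(sampleLabels(x))), c("leaf", "root"))
  expect_equal(unname(labelMeans(x)["g1", "leaf"]), 2)

  writeLines(c("gene_id\tleaf_R1", "g1\t-1"), f)
  expect_error(readExpressionMatrix(f), "negative")
  writeLines(c("gene_id\tleaf_R1", "g1\tabc"), f)
  expect_error(readExpressionMatrix(f), "non-numeric|missing")
  writeLines(c("gene_id\tleaf", "g1\t1"), f)
  expect_error(readExpressionMatrix(f), "_R<replicate>")
})
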