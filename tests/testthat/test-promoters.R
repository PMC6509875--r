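# 60 bp toy chromosome used across the window-arithmetic tests
toyChrom <- paste(rep(c("A", "C", "G", "T", "A", "C"), 10), collapse = "")
revComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}
writeToyBed <- function(records) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chr1", toyChrom), fa)
  bed <- file.path(dir, "toy.bed")
  writeLines(records, bed)
  list(fa = fa, bed = bed)
}

test_that("plus-strand promoter windows follow [tss - up, tss + down)", {
  f <- writeToyBed("chr1\t20\t30\tgeneA\t0\t+")
  pr <- extractPromoters(f$fa, f$bed, upstream = 10, downstream = 5)
  gr <- promoterRanges(pr)
  expect_identical(GenomicRanges::start(gr) - 1L, 10L)  # 0-based start
  expect_identical(GenomicRanges::end(gr), 25L)         # half-open end
  expect_identical(as.character(promoterSeqs(pr)[[1L]]),
                   substr(toyChrom, 11, 25))
  expect_identical(Biostrings::width(promoterSeqs(pr)),
                   unname(GenomicRanges::width(gr)))
})

test_that("minus-strand windows are shifted and reverse-complemented", {
  # TSS base 40 (0-based) on the minus strand: BED half-open end = 41
  f <- writeToyBed("chr1\t30\t41\tgeneB\t0\t-")
  pr <- extractPromoters(f$fa, f$bed, upstream = 10, downstream = 5)
  gr <- promoterRanges(pr)
  expect_identical(GenomicRanges::start(gr) - 1L, 36L)
  expect_identical(GenomicRanges::end(gr), 51L)
  expect_identical(as.character(promoterSeqs(pr)[[1L]]),
                   revComp(substr(toyChrom, 37, 51)))
})

test_that("windows are clipped at chromosome boundaries with a message", {
  f <- writeToyBed("chr1\t3\t10\tgeneC\t0\t+")
  expect_message(
    pr <- extractPromoters(f$fa, f$bed, upstream = 10, downstream = 5),
    "clipped 1")
  gr <- promoterRanges(pr)
  expect_identical(GenomicRanges::start(gr) - 1L, 0L)
  expect_identical(GenomicRanges::end(gr), 8L)
  expect_true(gr$clipped)
  expect_identical(Biostrings::width(promoterSeqs(pr)), 8L)
})

test_that("unknown chromosomes are skipped; empty result errors", {
  f <- writeToyBed(c("chr1\t20\t30\tgeneA\t0\t+",
                     "chrMissing\t5\t10\tgeneX\t0\t+"))
  expect_warning(pr <- extractPromoters(f$fa, f$bed, 10, 5), "chrMissing")
  expect_identical(geneIds(pr), "geneA")
  f2 <- writeToyBed("chrMissing\t5\t10\tgeneX\t0\t+")
  expect_error(suppressWarnings(extractPromoters(f2$fa, f2$bed, 10, 5)),
               "no genes")
})

test_that("multi-transcript genes resolve to the 5'-most TSS", {
  expect_identical(chooseTss(c(100, 150), c(500, 600), c("+", "+"))$tss, 100)
  expect_identical(chooseTss(c(10, 20), c(300, 280), c("-", "-"))$tss, 300)
  expect_identical(chooseTss(50, 80, "+")$tss, 50)
  expect_warning(res <- chooseTss(c(1, 2), c(5, 6), c("+", "-")), "strand")
  expect_null(res)
  # order of records must not matter
  expect_identical(chooseTss(c(150, 100), c(600, 500), c("+", "+"))$tss, 100)

  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); writeLines(c(">chr1", toyChrom), fa)
  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3",
    "chr1\ttoy\tgene\t16\t45\t.\t+\t.\tID=geneM;gene_id=geneM",
    "chr1\ttoy\tmRNA\t21\t45\t.\t+\t.\tID=t1;Parent=geneM;gene_id=geneM",
    "chr1\ttoy\tmRNA\t16\t40\t.\t+\t.\tID=t2;Parent=geneM;gene_id=geneM"),
    gff)
  pr <- extractPromoters(fa, gff, upstream = 5, downstream = 5)
  # 5'-most transcript starts at 0-based 15
  expect_identical(GenomicRanges::start(promoterRanges(pr)) - 1L, 10L)
})

test_that("opposite-strand extraction with swapped extents is reverse-complementary", {
  set.seed(7)
  for (rep in 1:5) {
    chrom <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    dir <- withr::local_tempdir()
    fa <- file.path(dir, "r.fa"); writeLines(c(">chr1", chrom), fa)
    bedP <- file.path(dir, "p.bed")
    bedM <- file.path(dir, "m.bed")
    t0 <- 40L
    writeLines(sprintf("chr1\t%d\t%d\tgP\t0\t+", t0, t0 + 5L), bedP)
    # minus-strand TSS base t0 - 1: BED half-open end = t0
    writeLines(sprintf("chr1\t%d\t%d\tgM\t0\t-", t0 - 8L, t0), bedM)
    u <- sample(3:12, 1); d <- sample(3:12, 1)
    sP <- as.character(promoterSeqs(extractPromoters(fa, bedP, u, d))[[1L]])
    sM <- as.character(promoterSeqs(extractPromoters(fa, bedM, d, u))[[1L]])
    expect_identical(sM, revComp(sP))
  }
})

test_that("promoter FASTA and BED outputs round-trip the regions", {
  f <- writeToyBed(c("chr1\t20\t30\tgeneA\t0\t+", "chr1\t30\t41\tgeneB\t0\t-"))
  pr <- extractPromoters(f$fa, f$bed, 10, 5)
  dir <- withr::local_tempdir()
  faOut <- file.path(dir, "prom.fa")
  bedOut <- file.path(dir, "prom.bed")
  writePromoterFasta(pr, faOut)
  writePromoterBed(pr, bedOut)
  reread <- Biostrings::readDNAStringSet(faOut)
  expect_identical(names(reread), geneIds(pr))
  expect_identical(as.character(reread), as.character(promoterSeqs(pr)))
  bed <- read.table(bedOut, sep = "\t")
  expect_identical(bed$V4, geneIds(pr))
  expect_identical(bed$V2, GenomicRanges::start(promoterRanges(pr)) - 1L)
  expect_identical(bed$V3, GenomicRanges::end(promoterRanges(pr)))
})
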