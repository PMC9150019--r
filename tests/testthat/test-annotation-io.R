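test_that("FASTA ingest normalizes case and RNA alphabet and rejects duplicates", {
  p <- write_tmp(c(">x", "acgu"), ".fa")
  expect_identical(read_fasta(p), c(x = "ACGT"))

  p2 <- write_tmp(c(">a desc ignored", "AC", ">b", "GT"), ".fa")
  expect_identical(read_fasta(p2), c(a = "AC", b = "GT"))

  p3 <- write_tmp(c(">a", "AC", ">a", "GG"), ".fa")
  expect_error(read_fasta(p3), "duplicate")
})

test_that("BED ingest converts coordinates, keeps multi-locus names, rejects bad rows", {
  p <- write_tmp("chr1\t10\t32\tmir-1\t0\t+", ".bed")
  gr <- read_bed(p)
  expect_identical(S4Vectors::mcols(gr)$id, "mir-1")
  expect_equal(GenomicRanges::start(gr), 11L)   # 0-based half-open -> 1-based
  expect_equal(GenomicRanges::end(gr), 32L)
  expect_identical(as.character(GenomicRanges::strand(gr)), "+")

  p2 <- write_tmp(c("chr1\t10\t30\tpir-7\t0\t+",
                    "chr2\t50\t70\tpir-7\t0\t-"), ".bed")
  gr2 <- read_bed(p2)
  expect_length(gr2, 2L)
  expect_identical(unique(S4Vectors::mcols(gr2)$id), "pir-7")

  expect_error(read_bed(write_tmp("chr1\t10\t10\tx\t0\t+", ".bed")),
               "invalid interval")
  expect_error(read_bed(write_tmp("chr1\t10\t20\tx\t0\t.", ".bed")),
               "strand")
})

test_that("fragment tables split coordinate and sequence-only rows", {
  hdr <- "id\tsequence\tchrom\tstart\tend\tstrand"
  p <- write_tmp(c(hdr,
                   "tRF-1\tACGTACGTACG\tchr1\t100\t111\t+",
                   "tRF-2\tACGTACGTACG\t\t\t\t"), ".tsv")
  ft <- read_fragment_table(p)
  expect_identical(names(ft$seqs), c("tRF-1", "tRF-2"))
  expect_length(ft$loci, 1L)
  expect_equal(GenomicRanges::start(ft$loci), 101L)
  expect_equal(GenomicRanges::end(ft$loci), 111L)
  expect_equal(GenomicRanges::width(ft$loci), nchar("ACGTACGTACG"))

  empty <- read_fragment_table(write_tmp(hdr, ".tsv"))
  expect_length(empty$seqs, 0L)
  expect_length(empty$loci, 0L)

  expect_error(read_fragment_table(write_tmp("id\tchrom", ".tsv")), "schema")
})

test_that("strand-aware extraction matches hand-derived substrings and reverse complements", {
  genome <- c(chr1 = "ACGTACGT")
  # 0-based (2,6,+) == internal 3..6
  expect_identical(extract_sequence(genome, genomic_interval("chr1", 3, 6, "+")),
                   "GTAC")
  expect_identical(extract_sequence(genome, genomic_interval("chr1", 1, 4, "-")),
                   "ACGT")   # revcomp("ACGT") happens to be itself
  expect_identical(extract_sequence(genome, genomic_interval("chr1", 2, 5, "-")),
                   "TACG")   # revcomp("CGTA")
  expect_error(extract_sequence(genome, genomic_interval("chr1", 5, 12, "+")),
               "beyond")
  expect_error(extract_sequence(genome, genomic_interval("chrX", 1, 4, "+")),
               "absent")
})

test_that("extraction length and minus-strand identity hold on random intervals", {
  set.seed(401)
  genome <- c(c1 = rand_dna(500), c2 = rand_dna(300))
  for (i in 1:50) {
    chrom <- sample(names(genome), 1)
    L <- nchar(genome[[chrom]])
    s <- sample(L - 50L, 1)
    e <- s + sample(18:45, 1)
    plus <- extract_sequence(genome, genomic_interval(chrom, s, e, "+"))
    minus <- extract_sequence(genome, genomic_interval(chrom, s, e, "-"))
    expect_identical(nchar(plus), e - s + 1L)
    expect_identical(minus, oracle_revcomp(plus))
  }
})

test_that("GTF emission uses 1-based inclusive coordinates and the exon device", {
  gr <- cons_gr("chr1", 11, 32, "+", "m1", seq = "X")
  p <- tempfile(fileext = ".gtf")
  write_gtf(gr, p)
  lines <- grep("^#", readLines(p), value = TRUE, invert = TRUE)
  f <- strsplit(lines, "\t")[[1]]
  expect_identical(f[3], "exon")
  expect_identical(f[4:5], c("11", "32"))   # 0-based (10,32) -> "11","32"

  two <- cons_gr(c("chr1", "chr2"), c(11, 101), c(32, 120), c("+", "-"),
                 c("m2", "m2"), seq = "Y")
  p2 <- tempfile(fileext = ".gtf")
  write_gtf(two, p2)
  lines2 <- grep("^#", readLines(p2), value = TRUE, invert = TRUE)
  expect_length(lines2, 2L)
  expect_true(all(grepl('transcript_id "m2"', lines2, fixed = TRUE)))

  p3 <- tempfile(fileext = ".gtf")
  write_gtf(GenomicRanges::GRanges(), p3)
  expect_true(all(grepl("^#", readLines(p3))))   # header comment only
})

test_that("GTF round trip recovers id, loci, strand for multi-locus transcripts", {
  gr <- suppressWarnings(c(cons_gr("chr2", 5, 30, "-", "a"),
                           cons_gr("chr1", 11, 32, "+", "b"),
                           cons_gr("chr1", 100, 130, "+", "b")))
  p <- tempfile(fileext = ".gtf")
  write_gtf(gr, p)
  back <- read_gtf(p)
  expect_length(back, 3L)
  key <- function(g) sort(sprintf("%s:%d-%d:%s:%s",
                                  S4Vectors::mcols(g)$transcript_id,
                                  GenomicRanges::start(g),
                                  GenomicRanges::end(g),
                                  as.character(GenomicRanges::strand(g)),
                                  as.character(GenomicRanges::seqnames(g))))
  expect_identical(key(back), key(gr))
  expect_identical(sum(S4Vectors::mcols(back)$transcript_id == "b"), 2L)
})

test_that("BED coordinate conversion is an involution", {
  gr <- genomic_interval(c("chr1", "chr2"), c(11, 200), c(32, 260),
                         c("+", "-"), id = c("x", "y"))
  p <- tempfile(fileext = ".bed")
  write_bed(gr, p)
  raw <- read.delim(p, header = FALSE)
  expect_equal(raw$V2, c(10L, 199L))       # back to 0-based
  back <- read_bed(p)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_identical(as.character(GenomicRanges::strand(back)),
                   as.character(GenomicRanges::strand(gr)))
})
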