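# small helper: a comparative-table-shaped row built directly
mk_row <- function(fasta, getfasta, chrom = "chr1", start = 10L,
                   end = start + nchar(getfasta) - 1L, strand = "+",
                   n_mappings = NA_integer_) {
  data.frame(id = "t", biotype = "mirna", chrom = chrom, start = start,
             end = end, strand = strand,
             length = if (is.na(chrom)) NA_integer_ else end - start + 1L,
             getfasta = getfasta,
             getfasta_rc = if (is.na(getfasta)) NA_character_
                           else oracle_revcomp(getfasta),
             fasta = fasta, orientation = NA_character_,
             fasta_matches_locus = identical(fasta, getfasta),
             n_mappings = n_mappings, hamming = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("case classification reproduces the six consensus relations", {
  expect_identical(classify_row(mk_row("ACGTAC", "ACGTAC"))$label, "MATCHED")
  expect_identical(classify_row(mk_row(NA_character_, "ACGTAC"))$label,
                   "LOCUS_ONLY")
  r <- mk_row("ACGTACGTACGTACGTAC", NA_character_, chrom = NA_character_,
              n_mappings = 2L)
  expect_identical(classify_row(r)$label, "FASTA_ONLY")
  r0 <- mk_row("ACGTACGTACGTACGTAC", NA_character_, chrom = NA_character_,
               n_mappings = 0L)
  expect_identical(classify_row(r0)$label, "UNRESOLVED")

  expect_identical(classify_row(mk_row("TTACGTACGG", "ACGTAC"))$label,
                   "EXT_LOCUS")
  expect_identical(classify_row(mk_row("CGTA", "ACGTAC"))$label, "EXT_FASTA")

  # suffix/prefix overlap of 4 nt: admitted only when min_overlap allows it
  both <- mk_row("GGACGT", "ACGTTT")
  expect_identical(classify_row(both, min_overlap = 4L)$label, "EXT_BOTH")
  expect_identical(classify_row(both, min_overlap = 8L)$label, "UNRESOLVED")

  # reverse orientation is tried after forward
  expect_identical(classify_row(mk_row(oracle_revcomp("ACGGTC"),
                                       "ACGGTC"))$label, "MATCHED")
})

test_that("equal-length mismatches are unresolved and carry their Hamming distance", {
  genome <- c(chr1 = "AAACGTACGTTTAAACCCGGGTTTACGT")
  loci <- genomic_interval("chr1", 4, 12, "+", id = "m1")
  fasta <- c(m1 = "CGTACGTTT")
  # plant 3 mismatches
  mut <- fasta
  substr(mut[["m1"]], 1, 1) <- "T"
  substr(mut[["m1"]], 5, 5) <- "A"  # C->A at pos 5? original "CGTACGTTT"[5]=C
  substr(mut[["m1"]], 9, 9) <- "A"
  names(mut) <- "m1"
  set <- annotation_set("db", "mirna", loci = loci, seqs = mut)
  rec <- reconcile_set(set, genome, index = build_genome_index(genome, k = 8))
  expect_identical(unname(rec$case_counts["UNRESOLVED"]), 1L)
  expect_identical(nrow(rec$unresolved), 1L)
  expect_identical(hamming_profile(rec$comparative), c(`3` = 1L))
})

test_that("locus-only records take the orientation-specified genome extract", {
  genome <- c(chr1 = "ACGTACGT")
  # 0-based (1,5,-) == internal 2..5; revcomp("CGTA") == "TACG"
  loci <- genomic_interval("chr1", 2, 5, "-", id = "L1")
  set <- annotation_set("db", "pirna", loci = loci)
  rec <- reconcile_set(set, genome)
  expect_identical(S4Vectors::mcols(rec$consensus)$sequence, "TACG")
  expect_identical(S4Vectors::mcols(rec$consensus)$case, "LOCUS_ONLY")
})

test_that("truncated loci are grown minimally so the extract equals the sequence", {
  genome <- c(chr1 = "AAACGTACGTTT")
  # 0-based (3,9,+) == internal 4..9 ("CGTACG"); fasta is the 9-mer around it
  loci <- genomic_interval("chr1", 4, 9, "+", id = "e1")
  set <- annotation_set("db", "mirna", loci = loci,
                        seqs = c(e1 = "ACGTACGTT"))
  rec <- reconcile_set(set, genome, index = build_genome_index(genome, k = 8))
  cons <- rec$consensus
  expect_identical(S4Vectors::mcols(cons)$case, "EXT_LOCUS")
  expect_equal(GenomicRanges::start(cons), 3L)    # 0-based (2,11)
  expect_equal(GenomicRanges::end(cons), 11L)
  expect_identical(extract_sequence(genome, cons), "ACGTACGTT")
})

test_that("sequence-only records adopt every exact placement as loci", {
  set.seed(407)
  core <- rand_dna(30)
  genome <- c(chr1 = paste0(rand_dna(200), core, rand_dna(150), core,
                            rand_dna(120)))
  set <- annotation_set("db", "pirna", seqs = c(f1 = core))
  rec <- reconcile_set(set, genome)
  cons <- rec$consensus
  expect_identical(unique(S4Vectors::mcols(cons)$transcript_id), "f1")
  expect_length(cons, 2L)
  expect_true(all(extract_sequence(genome, cons) == core))
  expect_identical(unname(rec$case_counts["FASTA_ONLY"]), 1L)
})

test_that("restricted mode admits only matched and sequence-only cases", {
  set.seed(408)
  genome <- c(chr1 = rand_dna(3000))
  g1 <- substr(genome[["chr1"]], 101, 130)
  g2 <- substr(genome[["chr1"]], 301, 330)
  loci <- genomic_interval(rep("chr1", 3), c(101, 301, 501),
                           c(130, 325, 530), rep("+", 3),
                           id = c("ok", "ext", "lonly"))
  seqs <- c(ok = g1, ext = substr(genome[["chr1"]], 301, 330),
            orphan = substr(genome[["chr1"]], 701, 730))
  set <- annotation_set("ucsc-like", "rrna", loci = loci, seqs = seqs)
  full <- reconcile_set(set, genome, mode = "full")
  expect_identical(unname(full$case_counts[c("MATCHED", "EXT_LOCUS",
                                             "LOCUS_ONLY", "FASTA_ONLY")]),
                   c(1L, 1L, 1L, 1L))
  res <- reconcile_set(set, genome, mode = "restricted")
  expect_identical(unname(res$case_counts[c("MATCHED", "FASTA_ONLY",
                                            "UNRESOLVED")]),
                   c(1L, 1L, 2L))
  expect_setequal(res$unresolved$id, c("ext", "lonly"))
})

test_that("planted case counts are recovered and records are conserved", {
  set.seed(409)
  genome <- c(cA = rand_dna(4000))
  gseq <- function(s, e) substr(genome[["cA"]], s, e)
  loci <- genomic_interval(rep("cA", 7),
                           c(101, 201, 301, 401, 501, 601, 701),
                           c(130, 230, 330, 430, 530, 625, 730),
                           rep("+", 7),
                           id = c("m1", "m2", "m3", "lo1", "lo2", "el1", "u1"))
  bad <- gseq(701, 730)
  substr(bad, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(bad, 5, 5))[1]
  seqs <- c(m1 = gseq(101, 130), m2 = gseq(201, 230), m3 = gseq(301, 330),
            el1 = gseq(601, 630),          # locus truncated by 5 nt
            f1 = gseq(801, 830), u1 = bad)
  set <- annotation_set("db", "mirna", loci = loci, seqs = seqs)
  rec <- reconcile_set(set, genome)
  expect_identical(unname(rec$case_counts[c("MATCHED", "LOCUS_ONLY",
                                            "FASTA_ONLY", "EXT_LOCUS",
                                            "UNRESOLVED")]),
                   c(3L, 2L, 1L, 1L, 1L))
  # conservation: every input record is a consensus record or unresolved
  n_cons <- length(unique(S4Vectors::mcols(rec$consensus)$transcript_id))
  expect_identical(length(set$ids), n_cons + nrow(rec$unresolved))
  # master invariant
  expect_identical(extract_sequence(genome, rec$consensus),
                   S4Vectors::mcols(rec$consensus)$sequence)
})

test_that("reconciling an already-consensus set is idempotent (all matched)", {
  set.seed(410)
  genome <- c(cA = rand_dna(4000))
  loci <- genomic_interval(rep("cA", 4), c(101, 201, 301, 401),
                           c(130, 235, 330, 440), c("+", "-", "+", "-"),
                           id = paste0("r", 1:4))
  set <- annotation_set("db", "mirna", loci = loci,
                        seqs = stats::setNames(extract_sequence(genome, loci),
                                               paste0("r", 1:4)))
  rec1 <- reconcile_set(set, genome)
  expect_identical(unname(rec1$case_counts["MATCHED"]), 4L)
  cons <- rec1$consensus
  set2 <- annotation_set("again", "mirna",
                         loci = {
                           g <- cons
                           S4Vectors::mcols(g) <- NULL
                           S4Vectors::mcols(g)$id <-
                             S4Vectors::mcols(cons)$transcript_id
                           g
                         },
                         seqs = stats::setNames(
                           S4Vectors::mcols(cons)$sequence,
                           S4Vectors::mcols(cons)$transcript_id))
  rec2 <- reconcile_set(set2, genome)
  expect_identical(unname(rec2$case_counts["MATCHED"]), 4L)
  expect_identical(GenomicRanges::start(rec2$consensus),
                   GenomicRanges::start(cons))
  expect_identical(S4Vectors::mcols(rec2$consensus)$sequence,
                   S4Vectors::mcols(cons)$sequence)
})

test_that("case labels are invariant under genome reverse-complement mirroring", {
  set.seed(411)
  genome <- c(cA = rand_dna(3000))
  L <- nchar(genome[["cA"]])
  loci <- genomic_interval(rep("cA", 3), c(101, 301, 501), c(130, 324, 530),
                           c("+", "-", "+"), id = c("a", "b", "c"))
  seqs <- c(a = extract_sequence(genome, loci[1]),
            b = extract_sequence(genome,
                                 genomic_interval("cA", 296, 324, "-")),
            c = rand_dna(30))
  set <- annotation_set("db", "mirna", loci = loci, seqs = seqs)
  rec <- reconcile_set(set, genome)

  # mirror: reverse-complement the chromosome and flip all strands
  genome_m <- c(cA = oracle_revcomp(genome[["cA"]]))
  loci_m <- genomic_interval(rep("cA", 3),
                             L - GenomicRanges::end(loci) + 1L,
                             L - GenomicRanges::start(loci) + 1L,
                             c("-", "+", "-"), id = c("a", "b", "c"))
  set_m <- annotation_set("db", "mirna", loci = loci_m, seqs = seqs)
  rec_m <- reconcile_set(set_m, genome_m)
  expect_identical(rec$case_counts, rec_m$case_counts)
})

test_that("every random sequence pair receives exactly one case label", {
  set.seed(412)
  labels <- character(0)
  for (i in 1:200) {
    g <- rand_dna(sample(10:40, 1))
    a <- switch(sample(4, 1),
                g,                                  # identical
                rand_dna(sample(10:40, 1)),         # unrelated
                substr(g, 2, nchar(g) - 1),         # nested
                paste0(rand_dna(5), g))             # contains g
    if (nchar(a) < 1) a <- "A"
    cls <- classify_row(mk_row(a, g))
    expect_true(cls$label %in% CASE_LABELS)
    labels <- c(labels, cls$label)
  }
  expect_gte(length(unique(labels)), 3L)  # the partition is exercised
})

test_that("hamming histograms count only equal-length mismatching rows", {
  rows <- rbind(mk_row("AAAA", "AAAA"), mk_row("AAAA", "AAAT"),
                mk_row("CCCC", "CCCG"), mk_row("AAGG", "ACGT"))
  rows$hamming <- c(NA, 1L, 1L, 3L)
  expect_identical(hamming_profile(rows), c(`1` = 2L, `3` = 1L))
  expect_length(hamming_profile(rows[1, ]), 0L)
})
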