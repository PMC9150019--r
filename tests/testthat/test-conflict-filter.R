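test_that("overlap witnesses match hand-worked examples and exclude abutment", {
  # 0-based (10,20) and (15,25) -> internal 11..20 and 16..25: overlap 5
  a <- cons_gr(c("chr1", "chr1"), c(11, 16), c(20, 25), c("+", "+"),
               c("x", "y"))
  wit <- find_intersections(a)
  expect_identical(nrow(wit), 1L)
  expect_identical(sort(c(wit$id_a, wit$id_b)), c("x", "y"))
  expect_identical(wit$overlap_bp, 5L)

  # 0-based (10,20) and (20,30): touching, not overlapping
  b <- cons_gr(c("chr1", "chr1"), c(11, 21), c(20, 30), c("+", "+"),
               c("x", "y"))
  expect_identical(nrow(find_intersections(b)), 0L)

  # overlap detection is strand-blind
  d <- cons_gr(c("chr1", "chr1"), c(11, 16), c(20, 25), c("+", "-"),
               c("x", "y"))
  expect_identical(nrow(find_intersections(d)), 1L)

  # a multi-locus transcript never witnesses against itself
  m <- cons_gr(c("chr1", "chr1"), c(11, 15), c(20, 28), c("+", "+"),
               c("m", "m"))
  expect_identical(nrow(find_intersections(m)), 0L)
})

test_that("in-database filtering removes both members and transitive chains", {
  three <- cons_gr(rep("chr1", 3), c(11, 16, 100), c(20, 25, 130),
                   rep("+", 3), c("x", "y", "z"))
  fi <- filter_inbase(three, "db")
  expect_identical(sort(fi$report$removed$id), c("x", "y"))
  expect_identical(S4Vectors::mcols(fi$survivors)$transcript_id, "z")

  # chain x-y, y-z with x,z disjoint: all three removed
  chain <- cons_gr(rep("chr1", 3), c(10, 18, 26), c(20, 28, 36),
                   rep("+", 3), c("x", "y", "z"))
  fc <- filter_inbase(chain, "db")
  expect_identical(sort(fc$report$removed$id), c("x", "y", "z"))
  expect_length(fc$survivors, 0L)

  disjoint <- cons_gr(rep("chr1", 3), c(10, 50, 90), c(20, 60, 100),
                      rep("+", 3), c("x", "y", "z"))
  fd <- filter_inbase(disjoint, "db")
  expect_identical(nrow(fd$report$removed), 0L)
  expect_length(fd$survivors, 3L)
})

test_that("inter-database filtering removes both sides but spares exempt biotypes", {
  sets <- list(
    trna = cons_gr("chr1", 100, 170, "+", "tRNA-Leu", biotype = "trna"),
    pirna = cons_gr(c("chr1", "chr2"), c(150, 500), c(175, 530),
                    c("+", "+"), c("piR-1", "piR-2"), biotype = "pirna"),
    tsrna = cons_gr("chr1", 120, 140, "+", "tRF-1", biotype = "tsrna"))
  fo <- filter_interbase(sets, exempt = "tsrna")
  expect_identical(sort(fo$report$removed$id), c("piR-1", "tRNA-Leu"))
  expect_length(fo$sets$trna, 0L)
  expect_identical(S4Vectors::mcols(fo$sets$pirna)$transcript_id, "piR-2")
  # the fragment inside the (removed) tRNA is untouched
  expect_identical(S4Vectors::mcols(fo$sets$tsrna)$transcript_id, "tRF-1")

  # biotypes on different chromosomes: nothing removed
  far <- list(trna = cons_gr("chr1", 100, 170, "+", "t1", biotype = "trna"),
              pirna = cons_gr("chr2", 100, 170, "+", "p1", biotype = "pirna"))
  expect_identical(nrow(filter_interbase(far)$report$removed), 0L)
})

test_that("single-side removal policy keeps the first-listed set's member", {
  sets <- list(
    trna = cons_gr("chr1", 100, 170, "+", "t1", biotype = "trna"),
    pirna = cons_gr("chr1", 150, 175, "+", "p1", biotype = "pirna"))
  ff <- filter_interbase(sets, exempt = character(0), policy = "first")
  expect_identical(ff$report$removed$id, "p1")
  expect_identical(S4Vectors::mcols(ff$sets$trna)$transcript_id, "t1")
})

test_that("filtering outcome is independent of set order and monotone", {
  set.seed(413)
  mk <- function(bt, n, chrom = "chr1") {
    s <- sort(sample(1000, n))
    cons_gr(rep(chrom, n), s, s + sample(20:60, n, replace = TRUE),
            rep("+", n), paste0(bt, "-", seq_len(n)), biotype = bt)
  }
  sets <- list(mirna = mk("mirna", 12), pirna = mk("pirna", 12),
               trna = mk("trna", 8))
  r1 <- filter_interbase(sets, exempt = character(0))
  r2 <- filter_interbase(rev(sets), exempt = character(0))
  ids <- function(r) sort(paste(r$report$removed$set, r$report$removed$id))
  expect_identical(ids(r1), ids(r2))

  # monotonicity: adding a record never resurrects a removed one
  extra <- c(sets$mirna, cons_gr("chr1", 400, 460, "+", "mirna-extra",
                                 biotype = "mirna"))
  r3 <- filter_interbase(list(mirna = extra, pirna = sets$pirna,
                              trna = sets$trna), exempt = character(0))
  expect_true(all(ids(r1) %in% ids(r3)))
})

test_that("interval intersection equals the brute-force all-pairs scan", {
  set.seed(414)
  for (i in 1:20) {
    n <- sample(30:200, 1)
    df <- data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                     start = sample(2000, n, replace = TRUE),
                     id = paste0("r", seq_len(n)),
                     stringsAsFactors = FALSE)
    df$end <- df$start + sample(10:80, n, replace = TRUE)
    gr <- cons_gr(df$chrom, df$start, df$end,
                  sample(c("+", "-"), n, replace = TRUE), df$id)
    got <- canon_witnesses(find_intersections(gr))
    want <- oracle_overlaps(df)
    expect_identical(got, want)
  }
})
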