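# Independent oracles and small builders shared across tests.
# These deliberately avoid the package's own index/overlap code paths:
# reverse complement via chartr, substring search via base-R regex
# lookahead (which reports overlapping matches), overlap detection via
# plain coordinate arithmetic.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all (overlapping) start positions of `pat` in `subject`
oracle_find_all <- function(subject, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), subject, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# every exact full-length placement of `q` on either strand of `genome`
# (named character vector); N in genome matches nothing because the
# pattern contains no N
oracle_align <- function(genome, q) {
  rows <- list()
  rc <- oracle_revcomp(q)
  for (chrom in names(genome)) {
    for (s in oracle_find_all(genome[[chrom]], q))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = s + nchar(q) - 1L, strand = "+",
        stringsAsFactors = FALSE)
    for (s in oracle_find_all(genome[[chrom]], rc))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = s + nchar(q) - 1L, strand = "-",
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

hits_as_df <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# O(n^2) all-pairs overlap scan on a table (chrom, start, end, id);
# same-id pairs excluded, >= 1 shared base, strand-blind; plain coordinate
# arithmetic over the full pair matrix
oracle_overlaps <- function(df) {
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      overlap_bp = integer(0), stringsAsFactors = FALSE)
  n <- nrow(df)
  if (n < 2L) return(empty)
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  ov <- pmin(df$end[i], df$end[j]) - pmax(df$start[i], df$start[j]) + 1L
  keep <- i < j & df$chrom[i] == df$chrom[j] & df$id[i] != df$id[j] &
    ov >= 1L
  if (!any(keep)) return(empty)
  pairs <- data.frame(id_a = df$id[i[keep]], id_b = df$id[j[keep]],
                      overlap_bp = ov[keep], stringsAsFactors = FALSE)
  swap <- pairs$id_a > pairs$id_b
  tmp <- pairs$id_a[swap]; pairs$id_a[swap] <- pairs$id_b[swap]
  pairs$id_b[swap] <- tmp
  pairs <- pairs[order(pairs$id_a, pairs$id_b, pairs$overlap_bp), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

canon_witnesses <- function(wit) {
  if (!nrow(wit))
    return(data.frame(id_a = character(0), id_b = character(0),
                      overlap_bp = integer(0), stringsAsFactors = FALSE))
  w <- wit[, c("id_a", "id_b", "overlap_bp")]
  swap <- w$id_a > w$id_b
  tmp <- w$id_a[swap]; w$id_a[swap] <- w$id_b[swap]; w$id_b[swap] <- tmp
  w <- w[order(w$id_a, w$id_b, w$overlap_bp), , drop = FALSE]
  rownames(w) <- NULL
  w
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

write_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# consensus-shaped GRanges from a compact spec table
cons_gr <- function(chrom, start, end, strand, id,
                    biotype = "mirna", seq = "ACGT") {
  gr <- genomic_interval(chrom, start, end, strand)
  S4Vectors::mcols(gr)$transcript_id <- id
  S4Vectors::mcols(gr)$biotype <- rep_len(biotype, length(gr))
  S4Vectors::mcols(gr)$case <- rep_len("MATCHED", length(gr))
  S4Vectors::mcols(gr)$sequence <- rep_len(seq, length(gr))
  S4Vectors::mcols(gr)$provenance <- rep_len("test", length(gr))
  gr
}
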