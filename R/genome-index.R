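#' Build an exact-match genome index
#'
#' A k-mer hash (seed-and-verify) over the forward genome. Queries are placed
#' by looking up their first k-mer and verifying the full-length ungapped
#' match; minus-strand placements are found by searching the query's reverse
#' complement. This reproduces, at the contract level, a short-read aligner
#' run with mismatch/gap penalties so high that only exact full-length
#' ungapped matches survive.
#'
#' `N` bases in the genome never match any query base, and k-mers containing
#' `N` are not indexed.
#'
#' @param genome Named character vector from [read_genome()].
#' @param k Seed length (>= 8); must not exceed the shortest query later
#'   submitted.
#' @return A `genome_index` object.
#' @export
build_genome_index <- function(genome, k = 12L) {
  k <- as.integer(k)
  if (k < 8L) stop("k must be >= 8")
  if (length(genome) == 0L || all(nchar(genome) == 0L))
    stop("cannot index an empty genome")
  kmer_chrom <- character(0); kmer_pos <- integer(0); kmers <- character(0)
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    if (!any(keep)) next
    kmers <- c(kmers, km[keep])
    kmer_pos <- c(kmer_pos, starts[keep])
    kmer_chrom <- c(kmer_chrom, rep(chrom, sum(keep)))
  }
  lookup <- split(seq_along(kmers), kmers)
  structure(list(genome = genome, k = k,
                 chrom = kmer_chrom, pos = kmer_pos, lookup = lookup),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index> %d chromosome(s), %s bp, k=%d\n",
              length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ","), x$k))
  invisible(x)
}

# candidate verification for one orientation; returns start positions per chrom
.verify_hits <- function(index, q) {
  k <- index$k
  seed <- substr(q, 1L, k)
  cand <- index$lookup[[seed]]
  if (is.null(cand)) return(list(chrom = character(0), start = integer(0)))
  chrom <- index$chrom[cand]
  st <- index$pos[cand]
  en <- st + nchar(q) - 1L
  lens <- nchar(index$genome)[chrom]
  ok <- en <= lens
  chrom <- chrom[ok]; st <- st[ok]; en <- en[ok]
  if (!length(st)) return(list(chrom = character(0), start = integer(0)))
  win <- substring(index$genome[chrom], st, en)
  hit <- win == q & !grepl("N", win, fixed = TRUE)
  list(chrom = chrom[hit], start = st[hit])
}

#' Place one query sequence exactly on the genome
#'
#' Reports every genomic interval, on either strand, whose strand-aware
#' extract equals the query with zero mismatches. Zero hits is a valid
#' result.
#'
#' @param index A [build_genome_index()] object.
#' @param seq Query sequence (A/C/G/T/N; N never matches).
#' @return `GRanges` of hits (possibly empty), strand-aware.
#' @export
align_exact <- function(index, seq) {
  seq <- normalize_seq(seq, "query")
  if (nchar(seq) < index$k)
    stop("lookup error: query shorter than index k (", index$k, ")")
  fwd <- .verify_hits(index, seq)
  rcq <- revcomp(seq)
  rev <- .verify_hits(index, rcq)
  chrom <- c(fwd$chrom, rev$chrom)
  st <- c(fwd$start, rev$start)
  sd <- c(rep("+", length(fwd$start)), rep("-", length(rev$start)))
  if (!length(st)) {
    gr <- GRanges()
    return(gr)
  }
  gr <- GRanges(chrom, IRanges(st, st + nchar(seq) - 1L), strand = sd)
  # deterministic order: chrom, start, strand
  lev <- unique(chrom)[natural_chrom_order(unique(chrom))]
  gr[order(match(as.character(seqnames(gr)), lev),
           GenomicRanges::start(gr), as.character(strand(gr)),
           method = "radix")]
}

#' Align a set of query sequences
#'
#' Queries with zero hits are retained with an empty hit list, mirroring an
#' alignment table that keeps unaligned reads on record.
#'
#' @param index A `genome_index`.
#' @param seqs Named character vector of queries.
#' @return An `alignment_table`: list with `hits` (named list of `GRanges`)
#'   and `n_mappings` (named integer).
#' @export
align_all <- function(index, seqs) {
  hits <- lapply(seqs, function(s) align_exact(index, s))
  structure(list(hits = hits,
                 n_mappings = vapply(hits, length, integer(1))),
            class = "alignment_table")
}

#' @export
print.alignment_table <- function(x, ...) {
  cat(sprintf("<alignment_table> %d queries, %d placed (rate %.3f)\n",
              length(x$hits), sum(x$n_mappings > 0),
              if (length(x$hits)) mean(x$n_mappings > 0) else NA_real_))
  invisible(x)
}

#' Overall alignment rate
#'
#' Fraction of queries with at least one exact genomic placement.
#'
#' @param table An `alignment_table`.
#' @return Numeric in `[0, 1]`.
#' @export
overall_alignment_rate <- function(table) {
  stopifnot(inherits(table, "alignment_table"))
  if (length(table$hits) == 0L)
    stop("alignment rate undefined for an empty table")
  mean(table$n_mappings > 0L)
}

#' Write an alignment table as TSV
#'
#' One row per hit (query_id, chrom, start, end, strand, n_mappings) in BED
#' coordinate convention (0-based half-open); unplaced queries appear with
#' empty coordinates and n_mappings 0.
#'
#' @param table An `alignment_table`.
#' @param path Output TSV.
#' @return Invisibly, the path.
#' @export
write_alignment_table <- function(table, path) {
  rows <- lapply(names(table$hits), function(id) {
    h <- table$hits[[id]]
    if (length(h) == 0L)
      return(data.frame(query_id = id, chrom = "", start = NA_integer_,
                        end = NA_integer_, strand = "",
                        n_mappings = 0L, stringsAsFactors = FALSE))
    data.frame(query_id = id,
               chrom = as.character(seqnames(h)),
               start = GenomicRanges::start(h) - 1L,
               end = GenomicRanges::end(h),
               strand = as.character(strand(h)),
               n_mappings = length(h), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(query_id = character(0), chrom = character(0),
                                    start = integer(0), end = integer(0),
                                    strand = character(0), n_mappings = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
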