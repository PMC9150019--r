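#' Read transcript sequences from FASTA
#'
#' Sequences are uppercased and RNA `U` is converted to `T` so that
#' comparisons against genome extracts are alphabet-consistent. The record
#' identifier is the first whitespace-delimited token of the header.
#'
#' @param path FASTA file path.
#' @return Named character vector (id -> sequence).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  xs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(xs))
  if (any(!nzchar(ids))) stop("FASTA parse error: empty header id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate transcript ID(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(xs)
  if (any(!nzchar(seqs))) {
    stop("FASTA parse error: empty sequence for record(s) ",
         paste(ids[!nzchar(seqs)], collapse = ", "), " in ", path)
  }
  seqs <- normalize_seq(seqs, what = paste0("FASTA ", path))
  names(seqs) <- ids
  seqs
}

#' Read transcript loci from BED6
#'
#' BED's 0-based half-open coordinates are converted to the internal 1-based
#' inclusive `GRanges` representation. Several lines sharing one name are the
#' multiple loci of a single transcript. Unstranded records (`.`) are
#' rejected: strand-aware sequence comparison is meaningless without strand.
#'
#' @param path BED file path (>= 6 columns).
#' @return `GRanges` with `mcols(.)$id` (one row per locus).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) return(genomic_interval(character(0), integer(0),
                                                integer(0), character(0),
                                                id = character(0)))
  if (any(width(gr) < 1L))
    stop("invalid interval in ", path, ": start >= end")
  sd <- as.character(strand(gr))
  if (any(!sd %in% c("+", "-")))
    stop("strand error in ", path,
         ": '.'/missing strand is not allowed; every locus must be '+' or '-'")
  ids <- mcols(gr)$name
  if (is.null(ids) || any(is.na(ids) | !nzchar(ids)))
    stop("BED name column (4) missing in ", path)
  out <- GRanges(as.character(seqnames(gr)),
                 IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
                 strand = sd)
  mcols(out)$id <- as.character(ids)
  out
}

#' Read a tRNA-fragment table (TSV)
#'
#' Header must name at least `id` and `sequence`; optional columns `chrom`,
#' `start`, `end`, `strand` carry a locus in BED convention (0-based
#' half-open). Rows with coordinates yield records with both locus and
#' sequence; rows without yield sequence-only records that the pipeline
#' places by exact genome alignment.
#'
#' @param path TSV file path.
#' @return List with `seqs` (named character) and `loci` (`GRanges` with id).
#' @export
read_fragment_table <- function(path) {
  if (!file.exists(path)) stop("fragment table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  need <- c("id", "sequence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("fragment table schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L)
    return(list(seqs = character(0),
                loci = genomic_interval(character(0), integer(0), integer(0),
                                        character(0), id = character(0))))
  ids <- df$id
  if (anyDuplicated(ids))
    stop("duplicate transcript ID(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- normalize_seq(df$sequence, what = paste0("fragment table ", path))
  names(seqs) <- ids
  has_coord_cols <- all(c("chrom", "start", "end", "strand") %in% names(df))
  if (!has_coord_cols) {
    loci <- genomic_interval(character(0), integer(0), integer(0),
                             character(0), id = character(0))
  } else {
    miss <- function(x) is.na(x) | !nzchar(trimws(x))
    with_loc <- !(miss(df$chrom) | miss(df$start) | miss(df$end) |
                    miss(df$strand))
    sub <- df[with_loc, , drop = FALSE]
    if (nrow(sub)) {
      st0 <- as.integer(sub$start)  # BED convention: 0-based half-open
      en0 <- as.integer(sub$end)
      if (any(is.na(st0) | is.na(en0)))
        stop("fragment table ", path, ": non-numeric coordinates")
      if (any(st0 >= en0))
        stop("invalid interval in ", path, ": start >= end")
      loci <- genomic_interval(sub$chrom, st0 + 1L, en0, sub$strand,
                               id = sub$id)
    } else {
      loci <- genomic_interval(character(0), integer(0), integer(0),
                               character(0), id = character(0))
    }
  }
  list(seqs = seqs, loci = loci)
}

#' Assemble an annotation set
#'
#' One source database of one biotype: loci (possibly several per transcript)
#' plus optional database-delivered sequences. Every record must carry at
#' least one locus or a sequence; duplicate sequence IDs are a hard error so
#' that case statistics cannot be corrupted by silent merging.
#'
#' @param name Source database label.
#' @param biotype One of [BIOTYPES].
#' @param genome_build Genome build tag (free text).
#' @param loci `GRanges` with `mcols(.)$id`, possibly empty.
#' @param seqs Named character vector of sequences, possibly empty.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(name, biotype, genome_build = "synthetic",
                           loci = NULL, seqs = character(0)) {
  biotype <- match.arg(biotype, BIOTYPES)
  if (is.null(loci))
    loci <- genomic_interval(character(0), integer(0), integer(0),
                             character(0), id = character(0))
  if (is.null(mcols(loci)$id) && length(loci) > 0L)
    stop("loci GRanges must carry mcols(.)$id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate transcript ID(s) in sequences of set '", name, "'")
  ids <- unique(c(mcols(loci)$id, names(seqs)))
  if (length(ids) == 0L && (length(loci) || length(seqs)))
    stop("records without identifiers in set '", name, "'")
  structure(list(name = name, biotype = biotype,
                 genome_build = genome_build,
                 loci = loci, seqs = seqs, ids = ids),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set '%s'> biotype=%s build=%s records=%d loci=%d seqs=%d\n",
              x$name, x$biotype, x$genome_build,
              length(x$ids), length(x$loci), length(x$seqs)))
  invisible(x)
}

#' Read an annotation set from files
#'
#' @param name,biotype,genome_build See [annotation_set()].
#' @param fasta,bed,table Optional paths: transcript FASTA, BED6 loci, or a
#'   fragment TSV (for tRNA-derived fragments). `table` is exclusive with
#'   `fasta`/`bed`.
#' @return An `annotation_set`.
#' @export
read_annotation_set <- function(name, biotype, genome_build = "synthetic",
                                fasta = NULL, bed = NULL, table = NULL) {
  if (!is.null(table)) {
    if (!is.null(fasta) || !is.null(bed))
      stop("give either 'table' or 'fasta'/'bed', not both")
    ft <- read_fragment_table(table)
    return(annotation_set(name, biotype, genome_build,
                          loci = ft$loci, seqs = ft$seqs))
  }
  seqs <- if (!is.null(fasta)) read_fasta(fasta) else character(0)
  loci <- if (!is.null(bed)) read_bed(bed) else NULL
  annotation_set(name, biotype, genome_build, loci = loci, seqs = seqs)
}

#' GTF exon lines for one consensus transcript
#'
#' Every locus of the transcript becomes one `exon` feature carrying the same
#' `transcript_id` (and `gene_id`), so downstream counters (featureCounts,
#' HTSeq) sum reads across all loci of the transcript.
#'
#' @param gr `GRanges` rows of one transcript with mcols `transcript_id`,
#'   `biotype`, `sequence`.
#' @param source GTF source column.
#' @return Character vector of GTF lines.
#' @export
group_loci_as_exons <- function(gr, source = "srnaforge") {
  if (length(gr) == 0L)
    stop("export error: record has no consensus loci")
  tid <- mcols(gr)$transcript_id
  if (length(unique(tid)) != 1L)
    stop("group_loci_as_exons expects rows of a single transcript")
  sprintf('%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; biotype "%s"; sequence "%s";',
          as.character(seqnames(gr)), source,
          GenomicRanges::start(gr), GenomicRanges::end(gr),
          as.character(strand(gr)),
          tid, tid, mcols(gr)$biotype, mcols(gr)$sequence)
}

#' Write consensus records as GTF
#'
#' Coordinates are 1-based inclusive per GTF2.2. Output is deterministically
#' sorted (natural chromosome order, start, transcript_id) so identical
#' inputs give byte-identical files.
#'
#' @param gr Consensus `GRanges` (one row per locus) with mcols
#'   `transcript_id`, `biotype`, `sequence`.
#' @param path Output file.
#' @param source GTF source column.
#' @return Invisibly, the path.
#' @export
write_gtf <- function(gr, path, source = "srnaforge") {
  header <- c("##description: integrated small RNA transcript annotation",
              "##format: gtf (1-based inclusive); multi-locus transcripts encoded as exon groups")
  if (length(gr) > 0L) {
    if (is.null(mcols(gr)$transcript_id) || is.null(mcols(gr)$sequence) ||
        is.null(mcols(gr)$biotype))
      stop("export error: consensus GRanges needs transcript_id, biotype, sequence")
    gr <- sort_consensus(gr)
    lines <- sprintf('%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; biotype "%s"; sequence "%s";',
                     as.character(seqnames(gr)), source,
                     GenomicRanges::start(gr), GenomicRanges::end(gr),
                     as.character(strand(gr)),
                     mcols(gr)$transcript_id, mcols(gr)$transcript_id,
                     mcols(gr)$biotype, mcols(gr)$sequence)
  } else {
    lines <- character(0)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Parse a GTF written by [write_gtf()]
#'
#' @param path GTF file.
#' @return Consensus-shaped `GRanges` with mcols `transcript_id`, `biotype`,
#'   `sequence`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) {
    out <- GRanges()
    mcols(out)$transcript_id <- character(0)
    mcols(out)$biotype <- character(0)
    mcols(out)$sequence <- character(0)
    return(out)
  }
  out <- GRanges(as.character(seqnames(gr)),
                 IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
                 strand = as.character(strand(gr)))
  mcols(out)$transcript_id <- as.character(mcols(gr)$transcript_id)
  mcols(out)$biotype <- as.character(mcols(gr)$biotype)
  mcols(out)$sequence <- as.character(mcols(gr)$sequence)
  out
}

#' Write a genome or sequence set as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  xs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(xs, path, width = 70L)
  invisible(path)
}

#' Write loci as BED6
#'
#' Internal 1-based inclusive coordinates are converted back to BED's
#' 0-based half-open convention.
#' @param gr `GRanges` with `mcols(.)$id`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bed <- function(gr, path) {
  if (length(gr) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = mcols(gr)$id,
                   score = 0L,
                   strand = as.character(strand(gr)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
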