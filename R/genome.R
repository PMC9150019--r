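#' @importFrom GenomicRanges GRanges start end strand seqnames width mcols mcols<- findOverlaps pintersect
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom GenomeInfoDb seqlevels
NULL

#' Supported small RNA biotypes
#' @export
BIOTYPES <- c("mirna", "pirna", "trna", "rrna", "tsrna")

#' Consensus case labels
#'
#' The six reconciliation outcomes plus \code{UNRESOLVED} for records whose
#' database sequence and genome-extracted sequence conflict beyond repair.
#' @export
CASE_LABELS <- c("MATCHED", "LOCUS_ONLY", "FASTA_ONLY",
                 "EXT_LOCUS", "EXT_FASTA", "EXT_BOTH", "UNRESOLVED")

# severity used to pick a record-level label for multi-locus transcripts:
# a matched locus is "better" than any corrected one
.case_severity <- c(MATCHED = 0L, LOCUS_ONLY = 1L, EXT_FASTA = 2L,
                    EXT_LOCUS = 3L, EXT_BOTH = 4L, FASTA_ONLY = 5L,
                    UNRESOLVED = 6L)

#' Read a reference genome from FASTA
#'
#' Returns the genome as a named character vector of uppercase chromosome
#' sequences (alphabet A/C/G/T/N). Names are the first whitespace-delimited
#' token of each FASTA header.
#'
#' @param path FASTA file path.
#' @return Named character vector, one element per chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0L) stop("genome FASTA is empty: ", path)
  seqs <- chartr("U", "T", toupper(as.character(xs)))
  names(seqs) <- sub("\\s.*$", "", names(xs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names in genome: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("genome contains non-ACGTN characters in: ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Strand-aware sequence extraction from a genome
#'
#' Extracts the nucleotide sequence covered by each interval; minus-strand
#' intervals return the reverse complement (the transcript-orientation
#' sequence, as \code{bedtools getfasta -s} would).
#'
#' @param genome Named character vector from [read_genome()].
#' @param gr A `GRanges` with strand strictly `+` or `-`.
#' @return Character vector, one sequence per range.
#' @export
extract_sequence <- function(genome, gr) {
  if (length(gr) == 0L) return(character(0))
  chrom <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chrom), names(genome))
  if (length(unknown))
    stop("chromosome(s) absent from genome: ", paste(unknown, collapse = ", "))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  if (any(st < 1L))
    stop("interval start below chromosome start")
  lens <- nchar(genome)[chrom]
  if (any(en > lens))
    stop("interval end beyond chromosome end on ",
         paste(unique(chrom[en > lens]), collapse = ", "))
  sd <- as.character(strand(gr))
  if (any(!sd %in% c("+", "-")))
    stop("unstranded interval: strand must be '+' or '-'")
  out <- substring(genome[chrom], st, en)
  neg <- sd == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  unname(out)
}

#' Construct a stranded genomic interval set
#'
#' Convenience constructor for internal 1-based inclusive coordinates with
#' strict validation (non-empty width, strand `+`/`-` only).
#'
#' @param chrom,start,end,strand Parallel vectors; coordinates 1-based
#'   inclusive.
#' @param id Optional transcript identifiers stored in `mcols(.)$id`.
#' @return A `GRanges`.
#' @export
genomic_interval <- function(chrom, start, end, strand, id = NULL) {
  if (any(start < 1L) || any(end < start))
    stop("invalid interval: need 1 <= start <= end")
  if (any(!strand %in% c("+", "-")))
    stop("strand must be '+' or '-' ('.' is not allowed)")
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  if (!is.null(id)) mcols(gr)$id <- id
  gr
}

# natural chromosome order: chr2 < chr10, alphabetic otherwise
natural_chrom_order <- function(x) {
  pre <- sub("([0-9]+)$", "", x)
  num <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", x)))
  num[!grepl("[0-9]+$", x)] <- NA_integer_
  order(pre, num, x, method = "radix")
}

# deterministic sort of a consensus GRanges: chrom natural, start, id
sort_consensus <- function(gr) {
  if (length(gr) == 0L) return(gr)
  chrom <- as.character(seqnames(gr))
  lev <- unique(chrom)[natural_chrom_order(unique(chrom))]
  o <- order(match(chrom, lev), GenomicRanges::start(gr),
             mcols(gr)$transcript_id, method = "radix")
  gr[o]
}

hamming_dist <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

normalize_seq <- function(x, what = "sequence") {
  x <- chartr("U", "T", toupper(x))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop(what, " contains characters outside A/C/G/T/U/N")
  x
}
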