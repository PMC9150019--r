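#' Completeness audit of one annotation set
#'
#' Partitions records by presence of loci and sequence, mirroring a
#' completeness table (loci and sequence / loci only / sequence only).
#'
#' @param set An [annotation_set()].
#' @return One-row `data.frame`: biotype, database, n_loci_and_seq,
#'   n_loci_only, n_seq_only.
#' @export
completeness <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  has_locus <- set$ids %in% mcols(set$loci)$id
  has_seq <- set$ids %in% names(set$seqs)
  data.frame(biotype = set$biotype, database = set$name,
             n_loci_and_seq = sum(has_locus & has_seq),
             n_loci_only = sum(has_locus & !has_seq),
             n_seq_only = sum(!has_locus & has_seq),
             stringsAsFactors = FALSE)
}

#' Loci-per-transcript histogram
#'
#' @param set An [annotation_set()].
#' @return Named integer vector (number of loci -> number of transcripts);
#'   sequence-only records count under `0`.
#' @export
loci_per_transcript <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  if (!length(set$ids)) return(stats::setNames(integer(0), character(0)))
  n <- table(factor(mcols(set$loci)$id, levels = set$ids))
  tt <- table(as.integer(n))
  stats::setNames(as.integer(tt), names(tt))
}

#' Length-difference profile of sequence vs genome extract
#'
#' Histogram of `nchar(fasta) - nchar(getfasta)` over comparative-table rows
#' carrying both sequences. Loci truncated by a 1-nt liftOver artifact show
#' up as a spike at `+1` (the database sequence is one base longer than the
#' extract at the damaged locus).
#'
#' @param rows Comparative table from [build_comparative_table()].
#' @return Named integer vector (signed difference -> count).
#' @export
length_diff_profile <- function(rows) {
  both <- !is.na(rows$fasta) & !is.na(rows$getfasta)
  if (!any(both)) return(stats::setNames(integer(0), character(0)))
  d <- nchar(rows$fasta[both]) - nchar(rows$getfasta[both])
  tt <- table(d)
  stats::setNames(as.integer(tt), names(tt))
}

#' Correction-event table across reconciled sets
#'
#' One row per source set with per-case record counts plus in-base and
#' inter-base removal counts — the per-database correction ledger.
#'
#' @param recons List of `reconciliation` objects.
#' @param inbase_removed Named integer (set name -> count), optional.
#' @param interbase_removed Named integer (set name -> count), optional.
#' @return `data.frame`, one row per set.
#' @export
correction_table <- function(recons, inbase_removed = NULL,
                             interbase_removed = NULL) {
  lookup0 <- function(v, n) {
    if (is.null(v) || is.na(v[n][1])) 0L else as.integer(v[[n]])
  }
  rows <- lapply(recons, function(r) {
    cc <- as.list(r$case_counts)
    names(cc) <- tolower(names(cc))
    data.frame(biotype = r$biotype, database = r$name, cc,
               inbase_removed = lookup0(inbase_removed, r$name),
               interbase_removed = lookup0(interbase_removed, r$name),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# serialize a named histogram deterministically for the JSON summary
.hist_as_list <- function(h) {
  if (!length(h)) return(stats::setNames(list(), character(0)))
  o <- order(suppressWarnings(as.numeric(names(h))))
  as.list(stats::setNames(as.integer(h[o]), names(h)[o]))
}
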