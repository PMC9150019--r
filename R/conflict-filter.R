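#' Find overlapping locus pairs
#'
#' Overlap is defined as at least one shared base on the same chromosome,
#' regardless of strand (small RNA reads are commonly quantified
#' strand-agnostically). Half-open abutment is not overlap. With `b` absent,
#' all overlapping pairs within `a` are returned, excluding a transcript
#' overlapping itself across its own multiple loci; with `b` present, all
#' cross-set pairs.
#'
#' @param a,b Consensus `GRanges` (mcols `transcript_id`); `b` optional.
#' @param ignore_strand Overlaps are strand-blind by default.
#' @return `data.frame` of witnesses: `id_a`, `id_b`, `chrom`, `overlap_bp`.
#' @export
find_intersections <- function(a, b = NULL, ignore_strand = TRUE) {
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      chrom = character(0), overlap_bp = integer(0),
                      stringsAsFactors = FALSE)
  if (length(a) == 0L || (!is.null(b) && length(b) == 0L)) return(empty)
  if (is.null(b)) {
    hits <- suppressWarnings(findOverlaps(a, a,
                                          ignore.strand = ignore_strand,
                                          minoverlap = 1L))
    q <- queryHits(hits); s <- subjectHits(hits)
    ids <- mcols(a)$transcript_id
    keep <- q < s & ids[q] != ids[s]
    q <- q[keep]; s <- s[keep]
    if (!length(q)) return(empty)
    ov <- width(suppressWarnings(pintersect(a[q], a[s], ignore.strand = TRUE)))
    out <- data.frame(id_a = ids[q], id_b = ids[s],
                      chrom = as.character(seqnames(a[q])),
                      overlap_bp = ov, stringsAsFactors = FALSE)
  } else {
    hits <- suppressWarnings(findOverlaps(a, b,
                                          ignore.strand = ignore_strand,
                                          minoverlap = 1L))
    q <- queryHits(hits); s <- subjectHits(hits)
    if (!length(q)) return(empty)
    ov <- width(suppressWarnings(pintersect(a[q], b[s], ignore.strand = TRUE)))
    out <- data.frame(id_a = mcols(a)$transcript_id[q],
                      id_b = mcols(b)$transcript_id[s],
                      chrom = as.character(seqnames(a[q])),
                      overlap_bp = ov, stringsAsFactors = FALSE)
  }
  # collapse duplicate witnesses from multi-locus pairs is NOT done: each
  # overlapping locus pair is its own witness
  out[order(out$id_a, out$id_b, out$chrom, out$overlap_bp,
            method = "radix"), , drop = FALSE]
}

.conflict_report <- function(kind, removed, witnesses) {
  structure(list(kind = kind, removed = removed, witnesses = witnesses),
            class = "conflict_report")
}

#' @export
print.conflict_report <- function(x, ...) {
  cat(sprintf("<conflict_report kind=%s> removed=%d witnesses=%d\n",
              x$kind, nrow(x$removed), nrow(x$witnesses)))
  invisible(x)
}

#' Remove in-database locus conflicts
#'
#' Every record participating in any within-set overlap is removed — both
#' members of each conflicting pair, and transitively every record with at
#' least one witness. A multi-locus transcript is removed if any of its loci
#' conflicts. Survivors are pairwise non-overlapping.
#'
#' @param gr Consensus `GRanges` of one set.
#' @param set_name Label recorded in the report.
#' @return List with `survivors` (`GRanges`) and `report`
#'   (a `conflict_report`).
#' @export
filter_inbase <- function(gr, set_name = "set") {
  wit <- find_intersections(gr)
  removed_ids <- sort(unique(c(wit$id_a, wit$id_b)))
  keep <- !(mcols(gr)$transcript_id %in% removed_ids)
  removed <- data.frame(set = if (length(removed_ids)) set_name else character(0),
                        id = removed_ids, stringsAsFactors = FALSE)
  list(survivors = gr[keep],
       report = .conflict_report("inbase", removed, wit))
}

#' Remove inter-database locus conflicts
#'
#' Cross-biotype overlaps among non-exempt biotypes remove, under the
#' default policy, both participating records: a read in the shared region
#' cannot be assigned to either transcript. Exempt biotypes (default
#' `tsrna`, whose fragments naturally share their parent tRNA's locus) are
#' neither checked nor pruned.
#'
#' @param sets Named list (biotype -> consensus `GRanges`).
#' @param exempt Biotypes excluded from conflict checking.
#' @param policy `"both"` removes both members of each conflicting pair;
#'   `"first"` keeps the member from the earlier-listed set (a
#'   sensitivity-analysis option; order-dependent by construction).
#' @return List with `sets` (filtered, same names) and `report`.
#' @export
filter_interbase <- function(sets, exempt = "tsrna",
                             policy = c("both", "first")) {
  policy <- match.arg(policy)
  stopifnot(all(exempt %in% c(names(sets), BIOTYPES)))
  active <- setdiff(names(sets), exempt)
  all_wit <- list()
  removed <- list()
  if (length(active) >= 2L) {
    combos <- utils::combn(active, 2L, simplify = FALSE)
    for (pair in combos) {
      a <- sets[[pair[1]]]; b <- sets[[pair[2]]]
      wit <- find_intersections(a, b)
      if (!nrow(wit)) next
      wit$biotype_a <- pair[1]; wit$biotype_b <- pair[2]
      all_wit[[length(all_wit) + 1L]] <- wit
      if (policy == "both") {
        removed[[length(removed) + 1L]] <-
          data.frame(set = pair[1], id = wit$id_a, stringsAsFactors = FALSE)
        removed[[length(removed) + 1L]] <-
          data.frame(set = pair[2], id = wit$id_b, stringsAsFactors = FALSE)
      } else {
        removed[[length(removed) + 1L]] <-
          data.frame(set = pair[2], id = wit$id_b, stringsAsFactors = FALSE)
      }
    }
  }
  removed <- if (length(removed)) unique(do.call(rbind, removed))
             else data.frame(set = character(0), id = character(0),
                             stringsAsFactors = FALSE)
  removed <- removed[order(removed$set, removed$id, method = "radix"), ,
                     drop = FALSE]
  rownames(removed) <- NULL
  witnesses <- if (length(all_wit)) do.call(rbind, all_wit)
               else data.frame(id_a = character(0), id_b = character(0),
                               chrom = character(0), overlap_bp = integer(0),
                               biotype_a = character(0),
                               biotype_b = character(0),
                               stringsAsFactors = FALSE)
  out_sets <- sets
  for (bt in active) {
    bad <- removed$id[removed$set == bt]
    gr <- sets[[bt]]
    out_sets[[bt]] <- gr[!(mcols(gr)$transcript_id %in% bad)]
  }
  list(sets = out_sets,
       report = .conflict_report("interbase", removed, witnesses))
}

#' Write a conflict report as TSV
#' @param report A `conflict_report`.
#' @param path Output TSV (the witness table; removed IDs are recoverable
#'   from it).
#' @return Invisibly, the path.
#' @export
write_conflict_report <- function(report, path) {
  wit <- report$witnesses
  wit <- cbind(kind = rep(report$kind, nrow(wit)), wit)
  utils::write.table(wit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
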