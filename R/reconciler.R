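#' @name reconciler
#' @title Sequence-locus reconciliation
#'
#' @description
#' The heart of the integration: each transcript record is compared against
#' the reference genome and classified into one of six consensus cases
#' (or left unresolved). A database-delivered sequence ("fasta sequence") is
#' compared with the strand-aware genome extract at the record's locus
#' ("getfasta sequence"), in forward orientation first and reverse
#' complement second:
#'
#' \itemize{
#'   \item \code{MATCHED} - sequences identical; both locus and sequence kept.
#'   \item \code{LOCUS_ONLY} - no database sequence; the genome extract
#'     becomes the consensus sequence.
#'   \item \code{FASTA_ONLY} - no locus; every exact genomic placement of the
#'     sequence becomes a consensus locus.
#'   \item \code{EXT_LOCUS} - the extract is a proper substring of the
#'     database sequence (typical of liftOver-truncated loci); the locus is
#'     grown on the genome until its extract equals the sequence, with
#'     minimal growth and leftward tie-break.
#'   \item \code{EXT_FASTA} - the database sequence is a proper substring of
#'     the extract; the extract becomes the consensus sequence.
#'   \item \code{EXT_BOTH} - a proper overlap (suffix/prefix, at least
#'     \code{min_overlap} nt) joins the two; the locus grows to the union
#'     span and the union string becomes the consensus sequence.
#'   \item \code{UNRESOLVED} - none of the above (e.g. equal-length
#'     sequences with mismatches); the record is filtered out.
#' }
#'
#' Every emitted consensus record satisfies the master invariant: the
#' strand-aware genome extract of each of its loci equals its consensus
#' sequence byte-for-byte.
NULL

# pure string relation between a database sequence `a` and a genome extract
# `g`; returns label plus the details needed to build the consensus
classify_relation <- function(a, g, min_overlap = 8L) {
  la <- nchar(a); lg <- nchar(g)
  if (a == g) return(list(label = "MATCHED"))
  if (lg < la) {
    # all (overlapping) occurrences of g inside a
    occ <- integer(0)
    for (i in seq_len(la - lg + 1L))
      if (substr(a, i, i + lg - 1L) == g) occ <- c(occ, i)
    if (length(occ)) return(list(label = "EXT_LOCUS", offsets = occ))
  } else if (la < lg) {
    if (grepl(a, g, fixed = TRUE)) return(list(label = "EXT_FASTA"))
  }
  vmax <- min(la, lg) - 1L
  if (vmax >= min_overlap) {
    for (v in seq(vmax, min_overlap)) {
      if (substr(a, la - v + 1L, la) == substr(g, 1L, v))
        return(list(label = "EXT_BOTH", dir = "a_then_g", v = v))
      if (substr(g, lg - v + 1L, lg) == substr(a, 1L, v))
        return(list(label = "EXT_BOTH", dir = "g_then_a", v = v))
    }
  }
  out <- list(label = "UNRESOLVED")
  if (la == lg) out$hamming <- hamming_dist(a, g)
  out
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' Build the comparative loci table
#'
#' One row per (transcript, locus) pair plus one row per locus-less
#' sequence-only record: locus coordinates, strand-aware genome extract and
#' its reverse complement, the database sequence (if any), whether they match
#' in either orientation, the number of exact genome placements of the
#' sequence, and the Hamming distance for equal-length mismatches (minimum
#' over the two orientations).
#'
#' @param set An [annotation_set()].
#' @param genome Named character vector from [read_genome()].
#' @param aln Optional `alignment_table` covering the set's sequences; built
#'   on the fly (via `index`) when absent.
#' @param index Optional prebuilt [build_genome_index()].
#' @return A `data.frame` (the comparative loci table).
#' @export
build_comparative_table <- function(set, genome, aln = NULL, index = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  if (is.null(aln) && length(set$seqs)) {
    if (is.null(index)) index <- build_genome_index(genome)
    aln <- align_all(index, set$seqs)
  }
  nmap <- if (!is.null(aln)) aln$n_mappings else integer(0)

  loci <- set$loci
  rows <- list()
  if (length(loci)) {
    gf <- extract_sequence(genome, loci)
    gfrc <- revcomp(gf)
    ids <- mcols(loci)$id
    fasta <- unname(set$seqs[ids])       # NA where no sequence
    n_mappings <- ifelse(ids %in% names(nmap), nmap[ids], NA_integer_)
    matches <- !is.na(fasta) & (fasta == gf | fasta == gfrc)
    orientation <- rep(NA_character_, length(loci))
    orientation[!is.na(fasta) & fasta == gf] <- "fwd"
    orientation[!is.na(fasta) & fasta != gf & fasta == gfrc] <- "rev"
    hamming <- rep(NA_integer_, length(loci))
    eqlen <- !is.na(fasta) & !matches & nchar(fasta) == nchar(gf)
    for (i in which(eqlen))
      hamming[i] <- min(hamming_dist(fasta[i], gf[i]),
                        hamming_dist(fasta[i], gfrc[i]))
    rows[[1]] <- data.frame(
      id = ids, biotype = set$biotype,
      chrom = as.character(seqnames(loci)),
      start = GenomicRanges::start(loci), end = GenomicRanges::end(loci),
      strand = as.character(strand(loci)),
      length = width(loci),
      getfasta = gf, getfasta_rc = gfrc, fasta = fasta,
      orientation = orientation, fasta_matches_locus = matches,
      n_mappings = as.integer(n_mappings), hamming = hamming,
      stringsAsFactors = FALSE)
  }
  orphan <- setdiff(names(set$seqs), mcols(loci)$id)
  if (length(orphan)) {
    rows[[length(rows) + 1L]] <- data.frame(
      id = orphan, biotype = set$biotype,
      chrom = NA_character_, start = NA_integer_, end = NA_integer_,
      strand = NA_character_, length = NA_integer_,
      getfasta = NA_character_, getfasta_rc = NA_character_,
      fasta = unname(set$seqs[orphan]),
      orientation = NA_character_, fasta_matches_locus = FALSE,
      n_mappings = as.integer(nmap[orphan]), hamming = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(id = character(0), biotype = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), getfasta = character(0),
                      getfasta_rc = character(0), fasta = character(0),
                      orientation = character(0),
                      fasta_matches_locus = logical(0),
                      n_mappings = integer(0), hamming = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify one comparative-table row
#'
#' @param row One-row `data.frame` from [build_comparative_table()].
#' @param min_overlap Minimum suffix/prefix overlap (nt) for `EXT_BOTH`.
#' @return List with `label` (one of [CASE_LABELS]), `orientation`
#'   (`"fwd"`/`"rev"`/`NA`), and relation details.
#' @export
classify_row <- function(row, min_overlap = 8L) {
  if (is.na(row$fasta)) return(list(label = "LOCUS_ONLY", orientation = NA))
  if (is.na(row$chrom)) {
    if (!is.na(row$n_mappings) && row$n_mappings >= 1L)
      return(list(label = "FASTA_ONLY", orientation = NA))
    return(list(label = "UNRESOLVED", orientation = NA,
                reason = "sequence-only record with no exact genome placement"))
  }
  rel <- classify_relation(row$fasta, row$getfasta, min_overlap)
  if (rel$label != "UNRESOLVED") {
    rel$orientation <- "fwd"
    return(rel)
  }
  rel_r <- classify_relation(row$fasta, row$getfasta_rc, min_overlap)
  if (rel_r$label != "UNRESOLVED") {
    rel_r$orientation <- "rev"
    return(rel_r)
  }
  rel$orientation <- NA
  rel$reason <- "sequence conflicts with genome extract in both orientations"
  rel
}

# consensus for one locus row; returns list(ok, gr, seq, prov) or
# list(ok = FALSE, reason = ...)
.locus_consensus <- function(row, cls, genome) {
  strand0 <- row$strand
  eff <- if (identical(cls$orientation, "rev")) flip_strand(strand0) else strand0
  note <- if (identical(cls$orientation, "rev")) "strand corrected" else NULL
  t_g <- if (identical(cls$orientation, "rev")) row$getfasta_rc else row$getfasta
  chromlen <- nchar(genome[[row$chrom]])
  mk <- function(start, end, seq, extra = NULL) {
    gr <- genomic_interval(row$chrom, start, end, eff)
    list(ok = TRUE, gr = gr, seq = seq,
         prov = paste(c(extra, note), collapse = "; "))
  }
  switch(cls$label,
    MATCHED = mk(row$start, row$end, row$fasta),
    LOCUS_ONLY = mk(row$start, row$end, row$getfasta,
                    extra = "sequence from genome extract"),
    EXT_FASTA = mk(row$start, row$end, t_g,
                   extra = "sequence extended to genome extract"),
    EXT_LOCUS = {
      la <- nchar(row$fasta)
      cand_start <- cand_end <- integer(0)
      for (p in cls$offsets) {
        if (eff == "+") {
          ns <- row$start - (p - 1L); ne <- ns + la - 1L
        } else {
          ne <- row$end + (p - 1L); ns <- ne - la + 1L
        }
        if (ns >= 1L && ne <= chromlen) {
          gr <- genomic_interval(row$chrom, ns, ne, eff)
          if (extract_sequence(genome, gr) == row$fasta) {
            cand_start <- c(cand_start, ns); cand_end <- c(cand_end, ne)
          }
        }
      }
      if (!length(cand_start))
        list(ok = FALSE,
             reason = "locus extension failed: sequence does not fit the genome around the locus")
      else {
        i <- which.min(cand_start)   # minimal-growth candidates tie-break leftward
        mk(cand_start[i], cand_end[i], row$fasta,
           extra = sprintf("locus extended by %d nt", la - row$length))
      }
    },
    EXT_BOTH = {
      la <- nchar(row$fasta); lg <- nchar(t_g); v <- cls$v
      ext <- la - v
      if (cls$dir == "a_then_g") {
        useq <- paste0(row$fasta, substr(t_g, v + 1L, lg))
        if (eff == "+") { ns <- row$start - ext; ne <- row$end }
        else { ns <- row$start; ne <- row$end + ext }
      } else {
        useq <- paste0(t_g, substr(row$fasta, v + 1L, la))
        if (eff == "+") { ns <- row$start; ne <- row$end + ext }
        else { ns <- row$start - ext; ne <- row$end }
      }
      if (ns < 1L || ne > chromlen)
        return(list(ok = FALSE,
                    reason = "union extension runs past chromosome boundary"))
      gr <- genomic_interval(row$chrom, ns, ne, eff)
      if (extract_sequence(genome, gr) != useq)
        return(list(ok = FALSE,
                    reason = "union sequence absent from genome at extended locus"))
      mk(ns, ne, useq,
         extra = sprintf("locus extended to %d nt union (overlap %d nt)",
                         nchar(useq), v))
    },
    stop("internal: no consensus rule for label ", cls$label)
  )
}

#' Reconcile one annotation set against the genome
#'
#' Orchestrates comparative table, per-locus classification and consensus
#' construction. In `mode = "restricted"` (the rRNA rule) only `MATCHED` and
#' `FASTA_ONLY` records are admitted; locus-only and all extension cases are
#' demoted to `UNRESOLVED`.
#'
#' Multi-locus transcripts are classified per locus; the record survives with
#' its resolvable loci, its record-level case is the worst surviving locus
#' label, and loci whose consensus sequence disagrees with the record's
#' consensus sequence are dropped with a provenance note.
#'
#' @param set An [annotation_set()].
#' @param genome Named character vector from [read_genome()].
#' @param index Optional prebuilt genome index (built on demand otherwise).
#' @param aln Optional precomputed `alignment_table` for the set's sequences.
#' @param mode `"full"` (all six cases) or `"restricted"` (matched and
#'   sequence-only cases alone).
#' @param min_overlap Minimum `EXT_BOTH` overlap in nt.
#' @return A `reconciliation`: list with `consensus` (`GRanges`, one row per
#'   locus; mcols `transcript_id`, `biotype`, `case`, `sequence`,
#'   `provenance`), `unresolved` (`data.frame` id/reason), `case_counts`
#'   (named integer over [CASE_LABELS]), `comparative` (the table), `aln`,
#'   `name`, `biotype`, `mode`.
#' @export
reconcile_set <- function(set, genome, index = NULL, aln = NULL,
                          mode = c("full", "restricted"), min_overlap = 8L) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "annotation_set"))
  if (is.null(aln) && length(set$seqs)) {
    if (is.null(index)) index <- build_genome_index(genome)
    aln <- align_all(index, set$seqs)
  }
  tab <- build_comparative_table(set, genome, aln = aln, index = index)

  restricted_block <- c("LOCUS_ONLY", "EXT_LOCUS", "EXT_FASTA", "EXT_BOTH")
  cons_rows <- list()
  unresolved <- list()
  rec_case <- character(0)

  for (id in set$ids) {
    rows <- tab[tab$id == id, , drop = FALSE]
    locus_rows <- rows[!is.na(rows$chrom), , drop = FALSE]
    prov0 <- sprintf("source=%s", set$name)

    if (nrow(locus_rows) == 0L) {
      row <- rows[1L, , drop = FALSE]
      cls <- classify_row(row, min_overlap)
      if (cls$label == "FASTA_ONLY") {
        hits <- aln$hits[[id]]
        gr <- hits
        mcols(gr) <- NULL
        cons_rows[[length(cons_rows) + 1L]] <- list(
          id = id, case = "FASTA_ONLY", gr = gr, seq = row$fasta,
          prov = paste(c(prov0,
                         sprintf("placed by exact alignment (%d hit%s)",
                                 length(gr), if (length(gr) > 1L) "s" else "")),
                       collapse = "; "))
        rec_case[id] <- "FASTA_ONLY"
      } else {
        unresolved[[length(unresolved) + 1L]] <-
          data.frame(id = id, reason = cls$reason %||%
                       "sequence-only record with no exact genome placement",
                     stringsAsFactors = FALSE)
        rec_case[id] <- "UNRESOLVED"
      }
      next
    }

    per_locus <- vector("list", nrow(locus_rows))
    for (i in seq_len(nrow(locus_rows))) {
      row <- locus_rows[i, , drop = FALSE]
      cls <- classify_row(row, min_overlap)
      if (mode == "restricted" && cls$label %in% restricted_block) {
        per_locus[[i]] <- list(ok = FALSE, label = "UNRESOLVED",
                               reason = sprintf(
                                 "restricted mode: %s case not admitted",
                                 cls$label))
        next
      }
      if (cls$label == "UNRESOLVED") {
        per_locus[[i]] <- list(ok = FALSE, label = "UNRESOLVED",
                               reason = cls$reason %||% "conflict")
        next
      }
      res <- .locus_consensus(row, cls, genome)
      if (!res$ok) {
        per_locus[[i]] <- list(ok = FALSE, label = "UNRESOLVED",
                               reason = res$reason)
      } else {
        res$label <- cls$label
        per_locus[[i]] <- res
      }
    }

    ok <- vapply(per_locus, `[[`, logical(1), "ok")
    if (!any(ok)) {
      reasons <- unique(vapply(per_locus, `[[`, character(1), "reason"))
      unresolved[[length(unresolved) + 1L]] <-
        data.frame(id = id, reason = paste(reasons, collapse = " | "),
                   stringsAsFactors = FALSE)
      rec_case[id] <- "UNRESOLVED"
      next
    }
    kept <- per_locus[ok]
    labels <- vapply(kept, `[[`, character(1), "label")
    # one consensus sequence per record: anchor on the best-severity locus
    best <- which.min(.case_severity[labels])
    ref_seq <- kept[[best]]$seq
    agree <- vapply(kept, function(x) identical(x$seq, ref_seq), logical(1))
    dropped_n <- sum(!ok) + sum(!agree)
    kept <- kept[agree]
    labels <- labels[agree]
    gr <- suppressWarnings(do.call(c, lapply(kept, `[[`, "gr")))
    case <- labels[which.max(.case_severity[labels])]
    prov <- unique(unlist(lapply(kept, function(x)
      if (nzchar(x$prov)) x$prov else NULL)))
    if (dropped_n > 0L)
      prov <- c(prov, sprintf("%d conflicting locus/loci dropped", dropped_n))
    cons_rows[[length(cons_rows) + 1L]] <- list(
      id = id, case = case, gr = gr, seq = ref_seq,
      prov = paste(c(prov0, prov), collapse = "; "))
    rec_case[id] <- case
  }

  consensus <- .assemble_consensus(cons_rows, set$biotype)
  unresolved <- if (length(unresolved)) do.call(rbind, unresolved)
                else data.frame(id = character(0), reason = character(0),
                                stringsAsFactors = FALSE)
  case_counts <- stats::setNames(integer(length(CASE_LABELS)), CASE_LABELS)
  tt <- table(factor(rec_case, levels = CASE_LABELS))
  case_counts[names(tt)] <- as.integer(tt)

  # master invariant: every consensus locus re-extracts to its sequence
  if (length(consensus)) {
    re <- extract_sequence(genome, consensus)
    stopifnot(identical(re, mcols(consensus)$sequence))
  }
  # conservation: records in == consensus records + unresolved
  stopifnot(length(set$ids) ==
              length(unique(mcols(consensus)$transcript_id)) + nrow(unresolved))

  structure(list(consensus = consensus, unresolved = unresolved,
                 case_counts = case_counts, comparative = tab, aln = aln,
                 name = set$name, biotype = set$biotype, mode = mode),
            class = "reconciliation")
}

.assemble_consensus <- function(cons_rows, biotype) {
  if (!length(cons_rows)) {
    gr <- GRanges()
    mcols(gr)$transcript_id <- character(0)
    mcols(gr)$biotype <- character(0)
    mcols(gr)$case <- character(0)
    mcols(gr)$sequence <- character(0)
    mcols(gr)$provenance <- character(0)
    return(gr)
  }
  grs <- lapply(cons_rows, function(x) {
    g <- x$gr
    mcols(g)$transcript_id <- x$id
    mcols(g)$biotype <- biotype
    mcols(g)$case <- x$case
    mcols(g)$sequence <- x$seq
    mcols(g)$provenance <- x$prov
    g
  })
  sort_consensus(suppressWarnings(do.call(c, grs)))
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation '%s'> biotype=%s mode=%s\n",
              x$name, x$biotype, x$mode))
  print(x$case_counts)
  invisible(x)
}

#' Hamming-distance histogram of equal-length mismatches
#'
#' Counts comparative-table rows whose database sequence and genome extract
#' have equal length but at least one mismatching position (in the better of
#' the two orientations).
#'
#' @param rows Comparative table from [build_comparative_table()].
#' @return Named integer vector (distance -> count), possibly empty.
#' @export
hamming_profile <- function(rows) {
  h <- rows$hamming[!is.na(rows$hamming)]
  if (!length(h)) return(stats::setNames(integer(0), character(0)))
  tt <- table(h)
  stats::setNames(as.integer(tt), names(tt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
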