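#' Plan a synthetic fixture
#'
#' The plan states, per biotype, how many records of each consensus case to
#' plant, plus the pathologies observed in real source databases: multi-locus
#' transcripts, 1-nt liftOver-style locus truncations, equal-length sequence
#' mismatches of known Hamming distance, in-database and inter-database
#' locus overlaps, and tRNA-derived fragments nested inside their parent
#' tRNA's locus. [make_fixture()] realizes the plan deterministically per
#' seed and emits a machine-readable truth table for exact recovery testing.
#'
#' @param seed Integer seed; the whole fixture is a pure function of it.
#' @param chrom_lengths Named integer vector of chromosome lengths (>= 1 kb).
#' @param cases Named list (biotype -> named integer over [CASE_LABELS])
#'   of record counts; `NULL` for the defaults described above.
#' @param n_multilocus Number of miRNA `MATCHED` records carrying two loci.
#' @param n_inbase_pairs In-database overlapping pairs planted in piRNA.
#' @param interbase_pairs List of biotype pairs, one cross-database
#'   overlapping record pair each.
#' @param n_liftover_shift How many `EXT_LOCUS` plants are exact 1-nt
#'   truncations (the liftOver signature); the rest are truncated by 2-4 nt.
#' @param hamming_k Named list (biotype -> integer vector) of planted
#'   mismatch distances; lengths must match the `UNRESOLVED` counts.
#' @param min_overlap Overlap floor used for `EXT_BOTH` plants.
#' @return A `fixture_plan` object.
#' @export
fixture_plan <- function(seed = 1L,
                         chrom_lengths = c(chrS1 = 12000L, chrS2 = 12000L,
                                           chrS3 = 12000L),
                         cases = NULL,
                         n_multilocus = 2L,
                         n_inbase_pairs = 3L,
                         interbase_pairs = list(c("pirna", "trna"),
                                                c("mirna", "pirna"),
                                                c("trna", "mirna")),
                         n_liftover_shift = 5L,
                         hamming_k = NULL,
                         min_overlap = 8L) {
  if (any(chrom_lengths < 1000L)) stop("chromosome lengths must be >= 1 kb")
  if (is.null(cases)) {
    cases <- list(
      mirna = c(MATCHED = 6L, LOCUS_ONLY = 3L, FASTA_ONLY = 3L,
                EXT_LOCUS = 3L, EXT_FASTA = 2L, EXT_BOTH = 2L,
                UNRESOLVED = 2L),
      pirna = c(MATCHED = 5L, LOCUS_ONLY = 2L, FASTA_ONLY = 2L,
                EXT_LOCUS = 4L, EXT_FASTA = 2L, EXT_BOTH = 2L,
                UNRESOLVED = 2L),
      trna = c(MATCHED = 6L, LOCUS_ONLY = 1L, FASTA_ONLY = 1L,
               EXT_FASTA = 1L, EXT_BOTH = 1L, UNRESOLVED = 1L),
      rrna = c(MATCHED = 3L, FASTA_ONLY = 2L),
      tsrna = c(MATCHED = 4L, FASTA_ONLY = 2L))
  }
  if (is.null(hamming_k)) {
    hamming_k <- list(mirna = c(1L, 2L), pirna = c(1L, 3L), trna = 2L)
  }
  for (bt in names(cases)) {
    unk <- setdiff(names(cases[[bt]]), CASE_LABELS)
    if (length(unk)) stop("plan error: unknown case label(s) ", unk)
    n_unres <- cases[[bt]]["UNRESOLVED"]
    n_unres <- if (is.na(n_unres)) 0L else n_unres
    n_k <- length(hamming_k[[bt]] %||% integer(0))
    if (n_k != n_unres)
      stop("plan error: hamming_k for ", bt, " must list ", n_unres,
           " distance(s)")
  }
  n_ext_locus <- sum(vapply(cases, function(x) {
    v <- x["EXT_LOCUS"]; if (is.na(v)) 0L else as.integer(v)
  }, integer(1)))
  if (n_liftover_shift > n_ext_locus)
    stop("plan error: n_liftover_shift exceeds total EXT_LOCUS plants")
  mm <- cases$mirna["MATCHED"]
  if (n_multilocus > 0L && (is.na(mm) || n_multilocus > mm))
    stop("plan error: n_multilocus exceeds miRNA MATCHED plants")
  if (length(interbase_pairs)) {
    for (p in interbase_pairs)
      if (!all(p %in% names(cases)) || "tsrna" %in% p)
        stop("plan error: interbase pairs must name non-exempt planted biotypes")
  }
  n_records <- sum(unlist(cases)) + 2L * n_inbase_pairs +
    2L * length(interbase_pairs)
  # rough capacity: every record may claim up to ~200 bp of genome
  if (n_records * 200L > sum(chrom_lengths) * 0.6)
    stop("plan error: too many records for the genome size")
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 cases = cases, n_multilocus = as.integer(n_multilocus),
                 n_inbase_pairs = as.integer(n_inbase_pairs),
                 interbase_pairs = interbase_pairs,
                 n_liftover_shift = as.integer(n_liftover_shift),
                 hamming_k = hamming_k,
                 min_overlap = as.integer(min_overlap)),
            class = "fixture_plan")
}

#' @export
print.fixture_plan <- function(x, ...) {
  cat(sprintf("<fixture_plan seed=%d> genome=%d bp, %d biotype(s)\n",
              x$seed, sum(x$chrom_lengths), length(x$cases)))
  invisible(x)
}

# ---- independent base-R screening helpers (no reconciler/aligner code) ----

.count_occ_one <- function(chrom_seq, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), chrom_seq, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# occurrences of `s` on either strand of the genome
.count_occurrences <- function(genome, s) {
  rc <- revcomp(s)
  tot <- 0L
  for (chrom_seq in genome) {
    tot <- tot + .count_occ_one(chrom_seq, s)
    if (rc != s) tot <- tot + .count_occ_one(chrom_seq, rc)
  }
  tot
}

.max_prefix_suffix_overlap <- function(a, g) {
  vmax <- min(nchar(a), nchar(g)) - 1L
  best <- 0L
  for (v in seq_len(max(vmax, 0L))) {
    if (substr(a, nchar(a) - v + 1L, nchar(a)) == substr(g, 1L, v))
      best <- max(best, v)
    if (substr(g, nchar(g) - v + 1L, nchar(g)) == substr(a, 1L, v))
      best <- max(best, v)
  }
  best
}

.rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# sample one element even from a length-1 vector
.pick <- function(x) x[sample.int(length(x), 1L)]

#' Generate a random genome
#'
#' Uniform A/C/G/T chromosomes, deterministic per seed.
#'
#' @param seed Integer seed.
#' @param lengths Named integer vector of chromosome lengths (>= 1 kb).
#' @return Named character vector of chromosome sequences.
#' @export
make_genome <- function(seed, lengths = c(chrS1 = 12000L, chrS2 = 12000L,
                                          chrS3 = 12000L)) {
  if (any(lengths < 1000L)) stop("chromosome lengths must be >= 1 kb")
  with_fixture_rng(seed, {
    stats::setNames(vapply(lengths, .rand_seq, character(1)), names(lengths))
  })
}

# run expr under a seeded, restored RNG state
with_fixture_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

#' Realize a fixture plan on disk
#'
#' Writes `genome.fa`, per-biotype transcript FASTA/BED files, a tRNA
#' fragment TSV, a ready-to-run `config.yaml`, the serialized `plan.json`
#' and the `truth.tsv` table recording, for every planted record, its
#' intended consensus case, final fate (kept / unresolved / inbase_removed /
#' interbase_removed), expected consensus loci and sequence. Regenerating
#' with the same seed reproduces byte-identical files.
#'
#' @param plan A [fixture_plan()].
#' @param dir Output directory (created).
#' @return List with `dir`, `plan`, `truth` (`data.frame`), `config`
#'   (path to `config.yaml`) and `genome`.
#' @export
make_fixture <- function(plan, dir) {
  stopifnot(inherits(plan, "fixture_plan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_fixture_rng(plan$seed, .make_fixture_impl(plan, dir))
}

.make_fixture_impl <- function(plan, dir) {
  chroms <- names(plan$chrom_lengths)
  lens <- plan$chrom_lengths

  # --- slot allocator: disjoint spans with generous gaps ---
  cursor <- stats::setNames(rep(200L, length(chroms)), chroms)
  turn <- 0L
  alloc <- function(len) {
    turn <<- turn + 1L
    chrom <- chroms[(turn - 1L) %% length(chroms) + 1L]
    s <- cursor[[chrom]]
    e <- s + len - 1L
    if (e > lens[[chrom]] - 200L)
      stop("plan error: genome too small for the requested records")
    cursor[[chrom]] <<- e + sample(40:80, 1L)
    list(chrom = chrom, start = s, end = e)
  }

  # --- pass 1: record skeletons (slots, lengths, parameters) ---
  specs <- list()
  edits <- list()   # genome overwrites for multi-locus duplication
  add_spec <- function(x) specs[[length(specs) + 1L]] <<- x

  ext_locus_counter <- 0L
  for (bt in names(plan$cases)) {
    cc <- plan$cases[[bt]]
    restricted <- bt == "rrna"
    ham <- plan$hamming_k[[bt]] %||% integer(0)
    ham_i <- 0L
    for (label in intersect(CASE_LABELS, names(cc))) {
      n <- cc[[label]]
      if (is.na(n) || n < 1L) next
      for (i in seq_len(n)) {
        id <- sprintf("%s-%s-%02d", bt, tolower(label), i)
        strand <- sample(c("+", "-"), 1L)
        if (bt == "tsrna") next   # fragments handled after tRNA parents
        spec <- list(id = id, biotype = bt, label = label, strand = strand)
        if (label == "MATCHED") {
          spec$slot <- alloc(sample(20:45, 1L))
          if (bt == "mirna" && i <= plan$n_multilocus) {
            spec$slot2 <- alloc(spec$slot$end - spec$slot$start + 1L)
            spec$strand2 <- sample(c("+", "-"), 1L)
            edits[[length(edits) + 1L]] <- list(from = spec$slot,
                                                strand = strand,
                                                to = spec$slot2,
                                                strand2 = spec$strand2)
          }
        } else if (label == "LOCUS_ONLY") {
          spec$slot <- alloc(sample(20:45, 1L))
        } else if (label == "FASTA_ONLY") {
          spec$slot <- alloc(sample(20:45, 1L))
        } else if (label == "EXT_LOCUS") {
          ext_locus_counter <- ext_locus_counter + 1L
          spec$slot <- alloc(sample(24:45, 1L))
          spec$shrink <- if (ext_locus_counter <= plan$n_liftover_shift) 1L
                         else sample(2:4, 1L)
        } else if (label == "EXT_FASTA") {
          spec$slot <- alloc(sample(24:45, 1L))
          spec$trim <- sample(1:3, 2L, replace = TRUE)  # left/right trims
          if (sum(spec$trim) < 1L) spec$trim[1] <- 1L
        } else if (label == "EXT_BOTH") {
          d <- sample(3:5, 1L)
          spec$d <- d; spec$d2 <- d          # equal so length diff is 0
          L <- sample((2L * d + plan$min_overlap + 2L):45, 1L)
          spec$slot <- alloc(L)
        } else if (label == "UNRESOLVED") {
          spec$slot <- alloc(sample(20:45, 1L))
          ham_i <- ham_i + 1L
          spec$k <- ham[[ham_i]]
        }
        if (restricted && label %in% c("LOCUS_ONLY", "EXT_LOCUS",
                                       "EXT_FASTA", "EXT_BOTH")) {
          spec$truth_case <- "UNRESOLVED"; spec$fate <- "unresolved"
        } else if (label == "UNRESOLVED") {
          spec$truth_case <- "UNRESOLVED"; spec$fate <- "unresolved"
        } else {
          spec$truth_case <- label; spec$fate <- "kept"
        }
        add_spec(spec)
      }
    }
  }

  # in-database conflict pairs (piRNA)
  for (i in seq_len(plan$n_inbase_pairs)) {
    l1 <- sample(22:40, 1L); l2 <- sample(22:40, 1L)
    o <- sample(1:(min(l1, l2) - 1L), 1L)
    region <- alloc(l1 + l2)
    s1 <- region$start; e1 <- s1 + l1 - 1L
    s2 <- e1 - o + 1L; e2 <- s2 + l2 - 1L
    for (j in 1:2) {
      add_spec(list(id = sprintf("pirna-inbase-%02d%s", i, letters[j]),
                    biotype = "pirna", label = "MATCHED",
                    strand = sample(c("+", "-"), 1L),
                    slot = list(chrom = region$chrom,
                                start = if (j == 1L) s1 else s2,
                                end = if (j == 1L) e1 else e2),
                    truth_case = "MATCHED", fate = "inbase_removed"))
    }
  }

  # inter-database conflict pairs
  for (i in seq_along(plan$interbase_pairs)) {
    pair <- plan$interbase_pairs[[i]]
    l1 <- sample(22:40, 1L); l2 <- sample(22:40, 1L)
    o <- sample(1:(min(l1, l2) - 1L), 1L)
    region <- alloc(l1 + l2)
    s1 <- region$start; e1 <- s1 + l1 - 1L
    s2 <- e1 - o + 1L; e2 <- s2 + l2 - 1L
    for (j in 1:2) {
      add_spec(list(id = sprintf("%s-interbase-%02d", pair[j], i),
                    biotype = pair[j], label = "MATCHED",
                    strand = sample(c("+", "-"), 1L),
                    slot = list(chrom = region$chrom,
                                start = if (j == 1L) s1 else s2,
                                end = if (j == 1L) e1 else e2),
                    truth_case = "MATCHED", fate = "interbase_removed"))
    }
  }

  # --- genome, then multi-locus duplication edits ---
  genome <- stats::setNames(vapply(lens, .rand_seq, character(1)), chroms)
  for (ed in edits) {
    src <- substr(genome[[ed$from$chrom]], ed$from$start, ed$from$end)
    tseq <- if (ed$strand == "+") src else revcomp(src)
    content <- if (ed$strand2 == "+") tseq else revcomp(tseq)
    substr(genome[[ed$to$chrom]], ed$to$start, ed$to$end) <- content
  }
  extract1 <- function(slot, strand) {
    s <- substr(genome[[slot$chrom]], slot$start, slot$end)
    if (strand == "+") s else revcomp(s)
  }

  # --- tRNA-derived fragments nested in MATCHED tRNA parents ---
  parents <- Filter(function(x) x$biotype == "trna" && x$label == "MATCHED" &&
                      x$fate == "kept", specs)
  # widen three parents to tRNA scale
  # (parents were allocated 20-45 nt; fragments need >= 30 nt, fine)
  cc_ts <- plan$cases$tsrna %||% integer(0)
  if (sum(cc_ts, na.rm = TRUE) > 0L && !length(parents))
    stop("plan error: tsRNA fragments need at least one kept MATCHED tRNA parent")
  frag_specs <- list()
  fi <- 0L
  for (label in intersect(c("MATCHED", "FASTA_ONLY"), names(cc_ts))) {
    n <- cc_ts[[label]]
    if (is.na(n) || n < 1L) next
    for (i in seq_len(n)) {
      fi <- fi + 1L
      par <- parents[[(fi - 1L) %% length(parents) + 1L]]
      pT <- extract1(par$slot, par$strand)
      pl <- nchar(pT)
      fl <- .pick(18:min(28L, pl - 2L))
      off <- .pick(seq_len(pl - fl + 1L))
      fseq <- substr(pT, off, off + fl - 1L)
      j <- off + fl - 1L
      if (par$strand == "+") {
        fs <- par$slot$start + off - 1L; fe <- par$slot$start + j - 1L
      } else {
        fs <- par$slot$end - j + 1L; fe <- par$slot$end - off + 1L
      }
      frag_specs[[length(frag_specs) + 1L]] <- list(
        id = sprintf("tsrna-%s-%02d", tolower(label), i), biotype = "tsrna",
        label = label, strand = par$strand,
        slot = list(chrom = par$slot$chrom, start = fs, end = fe),
        parent = par$id, truth_case = label, fate = "kept")
    }
  }
  specs <- c(specs, frag_specs)

  # --- pass 2: derive sequences/loci, screen with independent checks ---
  fasta <- list(); bed <- list(); tsv <- list(); truth <- list()
  add_bed <- function(id, bt, slot, strand)
    bed[[bt]] <<- rbind(bed[[bt]], data.frame(
      chrom = slot$chrom, start = slot$start, end = slot$end, id = id,
      strand = strand, stringsAsFactors = FALSE))
  add_fa <- function(id, bt, seq) {
    v <- fasta[[bt]] %||% character(0)
    v[id] <- seq
    fasta[[bt]] <<- v
  }
  loci_str <- function(slots, strands) {
    paste(sprintf("%s:%d-%d:%s",
                  vapply(slots, `[[`, "", "chrom"),
                  vapply(slots, function(x) x$start, integer(1)),
                  vapply(slots, function(x) x$end, integer(1)),
                  strands), collapse = ";")
  }
  add_truth <- function(id, bt, case, fate, slots, strands, seq, n_loci)
    truth[[length(truth) + 1L]] <<- data.frame(
      id = id, biotype = bt, case = case, fate = fate,
      n_loci = n_loci, loci = loci_str(slots, strands), seq = seq,
      stringsAsFactors = FALSE)

  must_unique <- function(s, what) {
    if (.count_occurrences(genome, s) != 1L)
      stop("fixture screening failed (", what,
           " not unique on genome); use another seed")
  }

  for (sp in specs) {
    bt <- sp$biotype; id <- sp$id
    g <- extract1(sp$slot, sp$strand)
    if (sp$label == "MATCHED" && bt != "tsrna") {
      add_fa(id, bt, g)
      add_bed(id, bt, sp$slot, sp$strand)
      slots <- list(sp$slot); strands <- sp$strand
      if (!is.null(sp$slot2)) {
        add_bed(id, bt, sp$slot2, sp$strand2)
        slots <- list(sp$slot, sp$slot2); strands <- c(sp$strand, sp$strand2)
      }
      add_truth(id, bt, sp$truth_case, sp$fate, slots, strands, g,
                length(slots))
    } else if (sp$label == "LOCUS_ONLY") {
      add_bed(id, bt, sp$slot, sp$strand)
      add_truth(id, bt, sp$truth_case, sp$fate, list(sp$slot), sp$strand,
                if (sp$fate == "kept") g else "", 1L)
    } else if (sp$label == "FASTA_ONLY" && bt != "tsrna") {
      must_unique(g, id)
      add_fa(id, bt, g)
      add_truth(id, bt, sp$truth_case, sp$fate, list(sp$slot), sp$strand, g,
                1L)
    } else if (sp$label == "EXT_LOCUS") {
      must_unique(g, id)
      # truncate the locus at the transcript 3' end by `shrink` nt
      d <- sp$shrink
      tr <- if (sp$strand == "+")
        list(chrom = sp$slot$chrom, start = sp$slot$start,
             end = sp$slot$end - d)
      else
        list(chrom = sp$slot$chrom, start = sp$slot$start + d,
             end = sp$slot$end)
      add_fa(id, bt, g)
      add_bed(id, bt, tr, sp$strand)
      if (sp$fate == "kept")
        add_truth(id, bt, sp$truth_case, sp$fate, list(sp$slot), sp$strand,
                  g, 1L)
      else
        add_truth(id, bt, sp$truth_case, sp$fate, list(tr), sp$strand, "",
                  1L)
    } else if (sp$label == "EXT_FASTA") {
      sub <- substr(g, 1L + sp$trim[1], nchar(g) - sp$trim[2])
      add_fa(id, bt, sub)
      add_bed(id, bt, sp$slot, sp$strand)
      if (sp$fate == "kept")
        add_truth(id, bt, sp$truth_case, sp$fate, list(sp$slot), sp$strand,
                  g, 1L)
      else
        add_truth(id, bt, sp$truth_case, sp$fate, list(sp$slot), sp$strand,
                  "", 1L)
    } else if (sp$label == "EXT_BOTH") {
      L <- nchar(g); d <- sp$d; d2 <- sp$d2
      fseq <- substr(g, 1L, L - d2)              # transcript 5' part
      locus <- if (sp$strand == "+")
        list(chrom = sp$slot$chrom, start = sp$slot$start + d,
             end = sp$slot$end)
      else
        list(chrom = sp$slot$chrom, start = sp$slot$start,
             end = sp$slot$end - d)
      gloc <- extract1(locus, sp$strand)         # transcript 3' part
      v <- L - d - d2
      ok <- .max_prefix_suffix_overlap(fseq, gloc) == v &&
        !grepl(fseq, gloc, fixed = TRUE) && !grepl(gloc, fseq, fixed = TRUE)
      if (!ok)
        stop("fixture screening failed (EXT_BOTH overlap ambiguous for ",
             id, "); use another seed")
      add_fa(id, bt, fseq)
      add_bed(id, bt, locus, sp$strand)
      if (sp$fate == "kept")
        add_truth(id, bt, sp$truth_case, sp$fate, list(sp$slot), sp$strand,
                  g, 1L)
      else
        add_truth(id, bt, sp$truth_case, sp$fate, list(locus), sp$strand,
                  "", 1L)
    } else if (sp$label == "UNRESOLVED") {
      mut <- .plant_mismatches(g, sp$k, genome, plan$min_overlap)
      add_fa(id, bt, mut)
      add_bed(id, bt, sp$slot, sp$strand)
      add_truth(id, bt, "UNRESOLVED", "unresolved", list(sp$slot),
                sp$strand, "", 1L)
    } else if (bt == "tsrna") {
      if (sp$label == "MATCHED") {
        tsv[[length(tsv) + 1L]] <- data.frame(
          id = id, sequence = g, chrom = sp$slot$chrom,
          start = sp$slot$start - 1L, end = sp$slot$end,
          strand = sp$strand, stringsAsFactors = FALSE)
      } else {                                   # FASTA_ONLY fragment
        must_unique(g, id)
        tsv[[length(tsv) + 1L]] <- data.frame(
          id = id, sequence = g, chrom = "", start = NA_integer_,
          end = NA_integer_, strand = "", stringsAsFactors = FALSE)
      }
      add_truth(id, bt, sp$truth_case, sp$fate, list(sp$slot), sp$strand, g,
                1L)
    }
  }

  # --- emit files ---
  paths <- list(genome = file.path(dir, "genome.fa"))
  write_fasta(genome, paths$genome)
  sources <- list()
  for (bt in names(plan$cases)) {
    if (bt == "tsrna") {
      df <- do.call(rbind, tsv)
      p <- file.path(dir, "tsrna.tsv")
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                         na = "")
      paths$tsrna_table <- p
      sources[[length(sources) + 1L]] <-
        list(name = "fragments-synthetic", biotype = "tsrna",
             table = "tsrna.tsv")
      next
    }
    src <- list(name = paste0(bt, "-synthetic"), biotype = bt)
    if (!is.null(fasta[[bt]])) {
      p <- file.path(dir, paste0(bt, ".fa"))
      write_fasta(fasta[[bt]], p)
      src$fasta <- basename(p)
      paths[[paste0(bt, "_fasta")]] <- p
    }
    if (!is.null(bed[[bt]])) {
      p <- file.path(dir, paste0(bt, ".bed"))
      gr <- genomic_interval(bed[[bt]]$chrom, bed[[bt]]$start,
                             bed[[bt]]$end, bed[[bt]]$strand,
                             id = bed[[bt]]$id)
      write_bed(gr, p)
      src$bed <- basename(p)
      paths[[paste0(bt, "_bed")]] <- p
    }
    sources[[length(sources) + 1L]] <- src
  }

  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$biotype, truth$id, method = "radix"), ,
                 drop = FALSE]
  rownames(truth) <- NULL
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cfg <- list(species = "synthetic", genome = "genome.fa", outdir = "out",
              min_overlap = plan$min_overlap, conflict_policy = "both",
              exempt = list("tsrna"), seed = plan$seed, sources = sources)
  paths$config <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, paths$config)

  plan_ser <- unclass(plan)
  plan_ser$chrom_lengths <- as.list(plan$chrom_lengths)
  plan_ser$cases <- lapply(plan$cases, as.list)
  plan_ser$hamming_k <- lapply(plan$hamming_k, as.integer)
  paths$plan <- file.path(dir, "plan.json")
  jsonlite::write_json(plan_ser, paths$plan, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  list(dir = dir, plan = plan, truth = truth, config = paths$config,
       genome = genome, paths = paths)
}

#' Compare a pipeline run against a fixture truth table
#'
#' Checks, record by record, that the pipeline recovered the planted
#' consensus case, the final fate (kept / unresolved / in-base removed /
#' inter-base removed), and — for records with a planted consensus — the
#' exact consensus loci and sequence. Also checks the survivor sets of the
#' integrated and per-biotype outputs against the truth fates.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @param truth The `truth` `data.frame` from [make_fixture()].
#' @return `data.frame` of discrepancies (`id`, `field`, `expected`, `got`);
#'   zero rows means exact recovery.
#' @export
verify_recovery <- function(bundle, truth) {
  mism <- list()
  note <- function(id, field, expected, got)
    mism[[length(mism) + 1L]] <<- data.frame(
      id = id, field = field, expected = as.character(expected),
      got = as.character(got), stringsAsFactors = FALSE)

  canon_loci <- function(gr) {
    s <- sprintf("%s:%d-%d:%s", as.character(seqnames(gr)),
                 GenomicRanges::start(gr), GenomicRanges::end(gr),
                 as.character(strand(gr)))
    paste(sort(s), collapse = ";")
  }
  canon_truth_loci <- function(x)
    paste(sort(strsplit(x, ";", fixed = TRUE)[[1]]), collapse = ";")

  # recovered case / fate / consensus per id
  rec_case <- character(0); rec_fate <- character(0)
  rec_loci <- character(0); rec_seq <- character(0)
  for (bt in names(bundle$recons)) {
    r <- bundle$recons[[bt]]
    cons <- r$consensus
    ids <- unique(mcols(cons)$transcript_id)
    for (id in ids) {
      rows <- cons[mcols(cons)$transcript_id == id]
      rec_case[id] <- mcols(rows)$case[1]
      rec_loci[id] <- canon_loci(rows)
      rec_seq[id] <- mcols(rows)$sequence[1]
    }
    rec_fate[ids] <- "kept"
    if (nrow(r$unresolved)) {
      rec_case[r$unresolved$id] <- "UNRESOLVED"
      rec_fate[r$unresolved$id] <- "unresolved"
    }
    rep <- bundle$inbase_reports[[bt]]
    if (!is.null(rep) && nrow(rep$removed))
      rec_fate[rep$removed$id] <- "inbase_removed"
  }
  ib <- bundle$interbase_report$removed
  if (nrow(ib)) rec_fate[ib$id] <- "interbase_removed"

  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    got_case <- rec_case[tr$id]
    if (is.na(got_case)) { note(tr$id, "present", "yes", "missing"); next }
    if (got_case != tr$case) note(tr$id, "case", tr$case, got_case)
    got_fate <- rec_fate[tr$id]
    if (got_fate != tr$fate) note(tr$id, "fate", tr$fate, got_fate)
    if (nzchar(tr$seq) && tr$case != "UNRESOLVED") {
      if (is.na(rec_seq[tr$id]) || rec_seq[tr$id] != tr$seq)
        note(tr$id, "sequence", tr$seq, rec_seq[tr$id])
      want <- canon_truth_loci(tr$loci)
      if (is.na(rec_loci[tr$id]) || rec_loci[tr$id] != want)
        note(tr$id, "loci", want, rec_loci[tr$id])
    }
  }

  # survivor sets of the emitted forms
  integrated_ids <- sort(unique(mcols(bundle$integrated)$transcript_id))
  want_integrated <- sort(truth$id[truth$fate == "kept"])
  if (!identical(integrated_ids, want_integrated))
    note("(integrated)", "survivor_set",
         paste(want_integrated, collapse = ","),
         paste(integrated_ids, collapse = ","))
  for (bt in names(bundle$per_biotype)) {
    got <- sort(unique(mcols(bundle$per_biotype[[bt]])$transcript_id))
    want <- sort(truth$id[truth$biotype == bt &
                            truth$fate %in% c("kept", "interbase_removed")])
    if (!identical(got, want))
      note(paste0("(biotype:", bt, ")"), "survivor_set",
           paste(want, collapse = ","), paste(got, collapse = ","))
  }

  if (!length(mism))
    return(data.frame(id = character(0), field = character(0),
                      expected = character(0), got = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, mism)
}

# mutate k positions of g, screened (independently of the reconciler) so the
# mutant keeps Hamming distance k in forward orientation, has no substring
# or >= min_overlap prefix/suffix relation with the extract in either
# orientation, and does not occur anywhere on the genome
.plant_mismatches <- function(g, k, genome, min_overlap) {
  grc <- revcomp(g)
  for (try in 1:100) {
    pos <- sample(nchar(g), k)
    mut <- strsplit(g, "")[[1]]
    for (p in pos) mut[p] <- sample(setdiff(c("A", "C", "G", "T"), mut[p]), 1L)
    mut <- paste(mut, collapse = "")
    h_rev <- hamming_dist(mut, grc)
    if (h_rev <= k) next
    if (.max_prefix_suffix_overlap(mut, g) >= min_overlap) next
    if (.max_prefix_suffix_overlap(mut, grc) >= min_overlap) next
    if (.count_occurrences(genome, mut) > 0L) next
    return(mut)
  }
  stop("fixture screening failed (mismatch plant); use another seed")
}
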