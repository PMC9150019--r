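#' Run the full annotation-integration pipeline
#'
#' Reads every configured source database, aligns orphan sequences, and
#' reconciles each set against the genome (restricted mode for rRNA by
#' default), then removes in-database conflicts per set and inter-database
#' conflicts across non-exempt biotypes, and finally emits three output
#' forms:
#'
#' 1. `integrated.gtf` - all biotypes, inter-database conflicts removed;
#' 2. `biotype/<biotype>.gtf` - one file per biotype with no inter-database
#'    filtering applied;
#' 3. `tsrna.gtf` - the tRNA-derived fragment annotation alone, never
#'    entered into conflict checks (fragments legitimately share their
#'    parent tRNA's locus).
#'
#' All outputs are deterministically sorted; identical inputs give
#' byte-identical trees.
#'
#' @param config A [validate_config()] result, a path to a YAML config, or
#'   an equivalent list.
#' @param outdir Output directory (overrides the config); `NULL` keeps the
#'   results in memory only.
#' @param quiet Suppress per-stage count logging.
#' @return A `pipeline_bundle`: sets, reconciliations, conflict reports,
#'   integrated / per-biotype / tsRNA-only consensus `GRanges`, the
#'   conservation ledger, and output paths (when written).
#' @export
run_pipeline <- function(config, outdir = NULL, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  say <- function(...) if (!quiet) message(sprintf(...))

  genome <- read_genome(cfg$genome)
  say("genome: %d chromosome(s), %d bp", length(genome), sum(nchar(genome)))

  sets <- list()
  for (src in cfg$sources) {
    set <- read_annotation_set(src$name, src$biotype,
                               genome_build = cfg$species,
                               fasta = src$fasta, bed = src$bed,
                               table = src$table)
    missing_chrom <- setdiff(as.character(seqnames(set$loci)), names(genome))
    if (length(missing_chrom))
      stop("coordinate error in set '", src$name, "': chromosome(s) ",
           paste(missing_chrom, collapse = ", "), " absent from genome")
    sets[[src$biotype]] <- set
  }

  all_seq_len <- unlist(lapply(sets, function(s) nchar(s$seqs)))
  index <- NULL
  if (length(all_seq_len)) {
    if (min(all_seq_len) < 8L)
      stop("data error: sequences shorter than 8 nt cannot be indexed")
    k <- max(8L, min(12L, min(all_seq_len)))
    index <- build_genome_index(genome, k = k)
  }

  recons <- list()
  for (bt in names(sets)) {
    src <- cfg$sources[[match(bt, vapply(cfg$sources, `[[`, "", "biotype"))]]
    mode <- src$mode %||% if (bt == "rrna") "restricted" else "full"
    recons[[bt]] <- reconcile_set(sets[[bt]], genome, index = index,
                                  mode = mode,
                                  min_overlap = cfg$min_overlap)
    say("reconciled %s (%s): %s", bt, mode,
        paste(names(recons[[bt]]$case_counts), recons[[bt]]$case_counts,
              sep = "=", collapse = " "))
  }

  exempt <- intersect(cfg$exempt, names(sets))
  inbase_reports <- list()
  post_inbase <- list()
  for (bt in names(sets)) {
    if (bt %in% exempt) {
      post_inbase[[bt]] <- recons[[bt]]$consensus
      next
    }
    fi <- filter_inbase(recons[[bt]]$consensus, set_name = bt)
    inbase_reports[[bt]] <- fi$report
    post_inbase[[bt]] <- fi$survivors
    say("inbase filter %s: removed %d record(s)", bt, nrow(fi$report$removed))
  }

  ib <- filter_interbase(post_inbase, exempt = exempt,
                         policy = cfg$conflict_policy)
  final_sets <- ib$sets
  say("interbase filter: removed %d record(s)", nrow(ib$report$removed))

  integrated <- sort_consensus(
    suppressWarnings(do.call(c, unname(final_sets[names(sets)]))))
  per_biotype <- post_inbase          # inter-base filtering NOT applied
  tsrna_only <- if ("tsrna" %in% names(post_inbase)) post_inbase[["tsrna"]]
                else NULL

  # conservation ledger: input == kept + unresolved + inbase + interbase
  n_rec <- function(gr) length(unique(mcols(gr)$transcript_id))
  ledger <- do.call(rbind, lapply(names(sets), function(bt) {
    input <- length(sets[[bt]]$ids)
    unres <- nrow(recons[[bt]]$unresolved)
    inb <- if (!is.null(inbase_reports[[bt]]))
             nrow(inbase_reports[[bt]]$removed) else 0L
    intb <- sum(ib$report$removed$set == bt)
    kept <- n_rec(final_sets[[bt]])
    data.frame(biotype = bt, database = sets[[bt]]$name, input = input,
               kept = kept, unresolved = unres, inbase_removed = inb,
               interbase_removed = intb, stringsAsFactors = FALSE)
  }))
  bad <- with(ledger, input != kept + unresolved + inbase_removed +
                interbase_removed)
  if (any(bad))
    stop("internal: conservation ledger violated for ",
         paste(ledger$biotype[bad], collapse = ", "))

  # post-filter soundness: non-exempt integrated output has zero overlaps
  non_exempt_gr <- suppressWarnings(do.call(c, unname(
    final_sets[setdiff(names(sets), exempt)])))
  if (!is.null(non_exempt_gr) && length(non_exempt_gr) &&
      nrow(find_intersections(non_exempt_gr)))
    stop("internal: overlaps remain among non-exempt biotypes after filtering")

  bundle <- structure(list(
    config = cfg, sets = sets, recons = recons,
    inbase_reports = inbase_reports, interbase_report = ib$report,
    integrated = integrated, per_biotype = per_biotype,
    tsrna_only = tsrna_only, ledger = ledger, paths = NULL),
    class = "pipeline_bundle")

  if (!is.null(cfg$outdir))
    bundle$paths <- write_bundle(bundle, cfg$outdir)
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle>\n")
  print(x$ledger)
  invisible(x)
}

#' Write all pipeline outputs
#'
#' @param bundle A `pipeline_bundle`.
#' @param outdir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "biotype"), showWarnings = FALSE)
  dir.create(file.path(outdir, "reports"), showWarnings = FALSE)
  paths <- list()

  paths$integrated <- file.path(outdir, "integrated.gtf")
  write_gtf(bundle$integrated, paths$integrated)
  for (bt in names(bundle$per_biotype)) {
    p <- file.path(outdir, "biotype", paste0(bt, ".gtf"))
    write_gtf(bundle$per_biotype[[bt]], p)
    paths[[paste0("biotype_", bt)]] <- p
  }
  if (!is.null(bundle$tsrna_only)) {
    paths$tsrna <- file.path(outdir, "tsrna.gtf")
    write_gtf(bundle$tsrna_only, paths$tsrna)
  }

  rep_dir <- file.path(outdir, "reports")
  comp <- do.call(rbind, lapply(bundle$sets, completeness))
  rownames(comp) <- NULL
  paths$completeness <- file.path(rep_dir, "completeness.tsv")
  utils::write.table(comp, paths$completeness, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  inb_rm <- vapply(bundle$recons, function(r) {
    rep <- bundle$inbase_reports[[r$biotype]]
    if (is.null(rep)) 0L else nrow(rep$removed)
  }, integer(1))
  names(inb_rm) <- vapply(bundle$recons, `[[`, "", "name")
  intb_rm <- vapply(bundle$recons, function(r)
    sum(bundle$interbase_report$removed$set == r$biotype), integer(1))
  names(intb_rm) <- names(inb_rm)
  corr <- correction_table(bundle$recons, inb_rm, intb_rm)
  paths$correction <- file.path(rep_dir, "correction.tsv")
  utils::write.table(corr, paths$correction, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  paths$ledger <- file.path(rep_dir, "ledger.tsv")
  utils::write.table(bundle$ledger, paths$ledger, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  comp_tab <- do.call(rbind, lapply(bundle$recons, function(r) {
    tab <- r$comparative
    cbind(database = rep(r$name, nrow(tab)), tab)
  }))
  rownames(comp_tab) <- NULL
  paths$comparative <- file.path(rep_dir, "comparative.tsv")
  utils::write.table(comp_tab, paths$comparative, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  for (bt in names(bundle$inbase_reports)) {
    p <- file.path(rep_dir, paste0("conflicts_inbase_", bt, ".tsv"))
    write_conflict_report(bundle$inbase_reports[[bt]], p)
    paths[[paste0("conflicts_inbase_", bt)]] <- p
  }
  paths$conflicts_interbase <- file.path(rep_dir, "conflicts_interbase.tsv")
  write_conflict_report(bundle$interbase_report, paths$conflicts_interbase)

  alns <- lapply(bundle$recons, `[[`, "aln")
  alns <- alns[!vapply(alns, is.null, logical(1))]
  if (length(alns)) {
    merged <- structure(list(
      hits = do.call(c, unname(lapply(alns, `[[`, "hits"))),
      n_mappings = do.call(c, unname(lapply(alns, `[[`, "n_mappings")))),
      class = "alignment_table")
    paths$alignment <- file.path(rep_dir, "alignment.tsv")
    write_alignment_table(merged, paths$alignment)
  }

  summary <- list(
    species = bundle$config$species,
    ledger = bundle$ledger,
    case_counts = lapply(bundle$recons, function(r) as.list(r$case_counts)),
    inbase_removed = lapply(bundle$inbase_reports,
                            function(r) nrow(r$removed)),
    interbase_removed = as.list(table(bundle$interbase_report$removed$set)),
    hamming_profile = lapply(bundle$recons,
                             function(r) .hist_as_list(hamming_profile(r$comparative))),
    length_diff_profile = lapply(bundle$recons,
                                 function(r) .hist_as_list(length_diff_profile(r$comparative))))
  paths$summary <- file.path(rep_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
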