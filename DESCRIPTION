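Package: srnaforge
Title: Consensus Integration of Small RNA Transcript Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconciles small RNA transcript records (miRNA, piRNA, tRNA,
    rRNA, tRNA-derived fragments) whose database-delivered sequences and
    genomic loci disagree. Each record is compared against the reference
    genome, classified into one of six consensus cases (matched, locus-only,
    sequence-only, and three locus/sequence extension cases), corrected
    where possible and filtered otherwise. In-database and inter-database
    locus overlaps are detected and removed, and the integrated annotation
    is written as GTF with multi-locus transcripts encoded as exon groups
    sharing one transcript_id so that read counts sum across loci. Includes
    an exact-match genome aligner for placing orphan sequences, diagnostic
    reports (completeness, loci-per-transcript, length-difference and
    Hamming profiles, correction-event ledgers), and a seeded synthetic
    fixture generator that plants every consensus case and conflict type
    with a machine-readable truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
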