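---
title: "Consensus integration of small RNA annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus integration of small RNA annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaforge)
```

## The problem

Public small RNA databases (miRNA, piRNA, tRNA, rRNA, tRNA-derived
fragments) describe a transcript by two partially redundant pieces of
evidence: a *sequence* distributed as FASTA, and a *genomic locus*
distributed as BED. In practice the two frequently disagree. Records carry
only one of the two; a transcript maps to several genomic loci; locus
coordinates are damaged by build-to-build coordinate translation (typically
truncated by a single nucleotide); and the sequence stored at a locus
differs outright from what the genome says there. On top of the
per-record problems, loci overlap *within* a database and *between*
databases of different RNA classes, making reads in the shared region
unassignable to a single transcript.

`srnaforge` reconciles each record against the reference genome, repairs
what is repairable, filters what is not, and emits a single integrated GTF
(plus per-biotype and fragment-only forms) suitable for genome-alignment
quantification with featureCounts- or HTSeq-style counters.

## The consensus procedure

For a record with locus $\ell$ and database sequence $f$, let $g(\ell)$ be
the strand-aware genome extract at $\ell$ (minus-strand loci yield the
reverse complement, i.e. the transcript-orientation sequence). Comparison
is done in forward orientation first, reverse complement second; the first
orientation that yields a workable relation wins, so palindromic ties are
deterministic. The relation between $f$ and $g(\ell)$ selects one of seven
outcomes:

| case | relation | consensus locus | consensus sequence |
|------|----------|-----------------|--------------------|
| `MATCHED` | $f = g(\ell)$ | $\ell$ | $f$ |
| `LOCUS_ONLY` | no $f$ | $\ell$ | $g(\ell)$ |
| `FASTA_ONLY` | no $\ell$, $f$ placeable | all exact placements of $f$ | $f$ |
| `EXT_LOCUS` | $g(\ell)$ proper substring of $f$ | $\ell$ grown so its extract equals $f$ | $f$ |
| `EXT_FASTA` | $f$ proper substring of $g(\ell)$ | $\ell$ | $g(\ell)$ |
| `EXT_BOTH` | proper suffix/prefix overlap $\ge$ `min_overlap` | $\ell$ grown to the union span | union string |
| `UNRESOLVED` | none of the above | — record filtered | — |

Whatever the path, every emitted record satisfies one master invariant:
**the strand-aware genome extract of each consensus locus equals the
consensus sequence byte-for-byte**. `EXT_LOCUS` growth is verified on the
genome (minimal total growth; ties broken to the leftmost genomic start,
the faithful correction for 1-nt coordinate-translation truncations, which
dominate this class in real data). `EXT_BOTH` unions are likewise
re-extracted after growth; if the genome does not actually carry the
overhang next to the locus, the record is demoted to `UNRESOLVED` rather
than emitted with an invariant violation. When only the reverse
orientation matches, the consensus locus strand is flipped (recorded in
provenance) so the invariant still holds.

Equal-length sequences that differ are never "almost" accepted: any
Hamming distance $\ge 1$ outside a substring/overlap relation is
`UNRESOLVED`. No public source states a tolerated mismatch level, so the
zero-tolerance rule is the only reading that keeps the master invariant
meaningful; the per-distance histogram (`hamming_profile()`) is reported
instead of silently absorbing the conflicts.

### Orphan sequence placement

Sequence-only records are placed with an exact-match genome index
(`build_genome_index()`, k-mer seed of the first `k` bases plus
full-length verification on both strands). This reproduces, at the
contract level, a short-read aligner run with prohibitive mismatch and gap
penalties: no mismatch, no clip, no gap, all placements reported. When a
sequence has several exact placements, *all* of them become loci of the
one transcript — discarding hits would silently lose signal, and the GTF
exon encoding (below) represents multi-locus transcripts natively. `N`
bases in the genome match nothing, conservatively. Queries shorter than
`k` raise an error at lookup time; `k` defaults to 12 and is automatically
lowered (not below 8) when a source contains shorter sequences.

### Multi-locus records

Loci of one transcript are classified independently. The record survives
with its resolvable loci; its record-level case is the worst surviving
locus label; loci whose consensus sequence disagrees with the record's
consensus sequence (possible for locus-only records whose extracts differ)
are dropped with a provenance note, because the master invariant forces a
single sequence per record.

### Restricted mode (rRNA)

rRNA sources mix locus naming conventions enough that only two evidence
paths are trusted: exact match and sequence-only placement. In
`mode = "restricted"` every `LOCUS_ONLY` and `EXT_*` outcome is demoted to
`UNRESOLVED`. The pipeline applies restricted mode to rRNA sources by
default; any source can opt in via the config.

### Conflict filtering

Overlap is $\ge 1$ shared base on the same chromosome, strand-blind
(small RNA reads are commonly quantified without strand, and a
strand-aware flag is exposed for sensitivity analysis). Half-open abutment
is not overlap.

* **In-database**: every record with at least one overlap witness is
  removed — both members of each pair, hence whole transitive chains.
  Partial retention of a multi-locus transcript would desynchronize
  sequence and loci, so one conflicting locus removes the whole record.
* **Inter-database**: cross-biotype overlaps among non-exempt biotypes
  remove both participants under the default policy: the shared region
  cannot be attributed to either class, and keeping one side would be an
  arbitrary choice. `conflict_policy = "first"` keeps the earlier-listed
  set's member instead; it is order-dependent by construction and exists
  only for sensitivity analysis.
* **Exemption**: tRNA-derived fragments legitimately overlap their parent
  tRNA and each other, so the `tsrna` biotype is exempt from *both*
  conflict stages — fragments are neither checked nor pruned, and never
  enter the integrated output's conflict ledger.

### Output forms and the exon device

Three GTFs are emitted: `integrated.gtf` (all biotypes, inter-database
conflicts removed), `biotype/<biotype>.gtf` (per-biotype, inter-database
filtering *not* applied, for single-class studies), and `tsrna.gtf`
(fragments only). Every locus of a transcript becomes one `exon` feature
sharing the transcript's `transcript_id` (and `gene_id`), so downstream
counters sum reads across all loci of a transcript. Attributes are fixed
to `gene_id`, `transcript_id`, `biotype`, `sequence`; released annotations
of this kind do not document an attribute schema, so this is a convention
of the package, not a reconstruction. Coordinates are 1-based inclusive
per GTF2.2; output is sorted (natural chromosome order, start,
transcript id) so identical inputs give byte-identical files.

## Coordinates

Internally every interval lives in a `GRanges` (1-based inclusive), the
native convention of the R/Bioconductor stack this package is built on.
BED's 0-based half-open coordinates are converted exactly once at ingest
and once at BED emission; GTF emission needs no conversion. A single
internal convention was the design goal — `GRanges` additionally buys
validated containers and the interval machinery behind
`find_intersections()`. Unstranded (`.`) BED records are rejected rather
than defaulted: strand-aware sequence comparison is meaningless without a
strand.

## Tunable parameters

| parameter | default | units | rationale |
|-----------|---------|-------|-----------|
| `min_overlap` (`EXT_BOTH`) | 8 | nt | below ~8 nt a suffix/prefix overlap between an 18–45 nt sequence pair is likely chance; gluing on it would fabricate transcripts |
| index `k` | 12 (floor 8) | nt | seed specificity vs. shortest admissible query |
| `conflict_policy` | `both` | — | shared regions are unassignable to either side |
| `exempt` | `tsrna` | — | fragments share their parent locus by biology |
| strand in overlap tests | ignored | — | matches strand-agnostic quantification practice |

## The synthetic fixture generator

`fixture_plan()` / `make_fixture()` build a seeded random genome (default
three 12 kb chromosomes) and per-biotype sources that plant, with known
ground truth: every consensus case (defaults give each label at least five
records package-wide), two-locus miRNA records (realized by duplicating
genome content), 1-nt locus truncations imitating coordinate-translation
damage (five by default, so the length-difference profile must show a
spike of exactly that size at +1), equal-length mismatches of chosen
Hamming distances, three overlapping in-database pairs, three
inter-database pairs, and fragments nested inside kept tRNA parents.
Sequence lengths are 18–45 nt (tRNA parents up to ~45 nt here; real tRNAs
are longer, which changes nothing structurally), matching small RNA length
scales.

Plants are *screened* with independent base-R string checks (occurrence
counts via regex lookahead, substring and overlap tests via plain
`substr` arithmetic) so the truth table is guaranteed by construction, not
by the package's own classifier; screening failures are astronomically
rare resampling events, never silent relabelings. The truth table records
each record's intended case, fate (kept, unresolved, in-base removed,
inter-base removed), consensus loci and sequence; `verify_recovery()`
compares a pipeline run against it field by field.

What the generator does **not** emulate: repeat structure and GC bias of
real genomes, sequencing errors, genuinely ambiguous multi-mapping piRNA
clusters, and database-scale record counts (hundreds of thousands of
piRNAs). Passing recovery tests therefore demonstrate correctness of the
reconciliation and filtering logic under every planted pathology, not
performance or behavior on the full pathological richness of real
databases.

## Validation problem sizes

The shipped test suite runs the full pipeline on twenty fixture seeds
(~75 records, ~36 kb genome each) and checks exact truth recovery,
consensus soundness, ledger conservation, and post-filter overlap freedom
on every run; the exact aligner is checked against a brute-force
both-strand scan on 200 random genome/query instances (genomes up to
60 kb, queries 18–45 nt) and the intersection detector against an
all-pairs scan on 100 instances of up to 1000 intervals. These sizes keep
the whole suite in the minutes range on one CPU while exercising every
code path; all sizes are plan parameters and scale up freely.

## Known limitations

* Exact matching only: a sequence that differs from the genome at every
  placement (polymorphism, sequencing error in the source) ends up
  `UNRESOLVED` rather than fuzzily placed. This is deliberate.
* The comparative table is materialized per source; at the scale of full
  piRNA databases (~10^6 loci) the per-record R loop in the reconciler
  would become the bottleneck and would want chunking.
* Conflict filtering treats all overlaps equally; no expression evidence
  or partial-locus trimming is consulted.
* `conflict_policy = "first"` is order-dependent by design and should not
  be used for production annotations.
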