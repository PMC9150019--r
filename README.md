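# srnaforge

Consensus integration of small RNA transcript annotations.

Public small RNA databases — miRNA, piRNA, tRNA, rRNA, and tRNA-derived
fragment (tsRNA/tRF) collections — describe each transcript by two pieces
of evidence that often disagree: a **sequence** (FASTA) and a **genomic
locus** (BED). Records miss one of the two, transcripts map to multiple
loci, build-to-build coordinate translation truncates loci (typically by a
single nucleotide), stored sequences mismatch the genome at their own
locus, and loci overlap within and between databases, making reads in the
shared region unassignable. `srnaforge` is for anyone who wants to
quantify small RNAs by genome alignment (featureCounts/HTSeq style) and
needs one clean, conflict-free annotation rather than five inconsistent
ones.

## The method

For each record with locus ℓ and database sequence *f*, the strand-aware
genome extract *g(ℓ)* is compared with *f* (forward orientation first,
reverse complement second) and the record is classified:

* **MATCHED** — *f* = *g(ℓ)*: keep both.
* **LOCUS_ONLY** — no *f*: the extract becomes the consensus sequence.
* **FASTA_ONLY** — no ℓ: every exact genomic placement of *f* (found by a
  k-mer seed-and-verify exact matcher, both strands, no mismatches/gaps/
  clips) becomes a consensus locus.
* **EXT_LOCUS** — *g(ℓ)* is a proper substring of *f* (the liftOver
  signature): the locus is grown minimally on the genome until its extract
  equals *f*.
* **EXT_FASTA** — *f* is a proper substring of *g(ℓ)*: the extract wins.
* **EXT_BOTH** — a suffix/prefix overlap ≥ 8 nt joins the two: the locus
  grows to the union span, the union string is the sequence.
* **UNRESOLVED** — anything else (e.g. equal-length mismatches): filtered
  out, with a Hamming-distance histogram reported.

Every emitted record satisfies the invariant *extract(locus) == sequence*,
re-verified on the genome. Afterwards, overlapping loci (≥ 1 shared base,
strand-blind) are removed **within** each database and then **between**
biotypes — both members of each conflicting pair, since the shared region
belongs to neither. tRNA fragments are exempt: they legitimately share
their parent tRNA's locus. Three GTF forms are written (integrated,
per-biotype without inter-database filtering, fragments-only), with every
locus of a transcript encoded as an `exon` feature under one
`transcript_id` so counts sum across loci.

## Worked example

The package ships a seeded fixture generator that plants every consensus
case and conflict type with a machine-readable truth table:

```r
library(srnaforge)
fx <- make_fixture(fixture_plan(seed = 11), "demo")
b  <- run_pipeline(fx$config, outdir = "demo/out")
b$ledger
```

```
reconciled pirna (full): MATCHED=13 LOCUS_ONLY=2 FASTA_ONLY=2 EXT_LOCUS=4 EXT_FASTA=2 EXT_BOTH=2 UNRESOLVED=2
inbase filter pirna: removed 6 record(s)
interbase filter: removed 6 record(s)
  biotype            database input kept unresolved inbase_removed interbase_removed
1   mirna     mirna-synthetic    23   19          2              0                 2
2   pirna     pirna-synthetic    27   17          2              6                 2
3    trna      trna-synthetic    13   10          1              0                 2
4    rrna      rrna-synthetic     5    5          0              0                 0
5   tsrna fragments-synthetic     6    6          0              0                 0
```

The ledger is conservative by construction: for every source,
`input == kept + unresolved + inbase_removed + interbase_removed`. Of the
27 piRNA records, 2 had sequences conflicting with the genome at their
locus (unresolved), 6 formed three overlapping in-database pairs, and 2
collided with other biotypes; the 4 `EXT_LOCUS` records had truncated loci
that were grown back so that their genome extract equals the database
sequence. `verify_recovery(b, fx$truth)` returns a zero-row data frame:
every planted case, fate, locus and sequence was recovered exactly.

The integrated output looks like:

```
chrS1  srnaforge  exon  200  220  .  -  .  gene_id "mirna-matched-01"; transcript_id "mirna-matched-01"; biotype "mirna"; sequence "GATATAGTATTGCCCATCGAC";
```

Real sources are wired in through a declarative YAML config (one genome,
one source block per biotype with `fasta`/`bed` or a fragment `table`);
see `?validate_config`. A thin CLI is available after install:
`exec/srnaforge build|audit|simulate`.

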