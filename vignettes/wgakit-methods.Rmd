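---
title: "Alignment model, conversion semantics and validation design in wgakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment model, conversion semantics and validation design in wgakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgakit)
```

# The problem

Whole-genome aligners emit pairwise alignments in three mutually
incompatible dialects. MAF stores full gapped sequence rows per block
with *strand-relative* starts; PAF stores twelve tab-separated columns
with *forward-strand* query intervals and an optional `cg:Z:` CIGAR tag;
UCSC Chain stores gapless blocks as `(size, dt, dq)` triples with
minus-strand query coordinates counted on the reverse complement.
`wgakit` treats all three as views of one canonical
`AlignmentRecord`, so every conversion is a composition of two
well-tested maps rather than one of six ad hoc translators.

# The canonical model

An `AlignmentRecord` holds names, sequence sizes, 0-based half-open
intervals on the forward strand of both sequences, the query's strand
relative to the always-forward target, a normalized `Cigar`, and
optionally the two gapped alignment rows. The CIGAR alphabet is
`=` (match), `X` (mismatch), `M` (match-or-mismatch, as emitted by
chains and CIGAR dialects that do not distinguish), `I` (insertion,
consumes query only) and `D` (deletion, consumes target only). `I`
consuming the query is the PAF/minimap2 reading; the class validity
methods enforce that interval widths equal consumed bases on both sides,
so a malformed conversion fails at construction, not downstream.

Normalization means adjacent runs of one kind are merged and zero-length
runs dropped; this makes CIGAR equality a meaningful test of conversion
exactness.

Three choices here were genuinely open and are fixed as follows:

* **`M` resolution.** `M` is retained on input; any conversion with
  sequence available (a `SequenceStore` built from FASTA) resolves it
  into `=`/`X` by comparing bases. Without sequence, `M` passes through
  untouched, which is what keeps PAF↔Chain round trips lossless when no
  FASTA is at hand.
* **Base comparison.** Case-insensitive; `N` against anything —
  including another `N` — classifies as a mismatch. An `N` asserts an
  unknown base, so claiming a match would overstate identity; the choice
  is visible in `cigarFromTexts` and tested.
* **Row order.** The first MAF `s` row is the target/reference, the
  convention of common pairwise-MAF emitters. Blocks whose *target* row
  is on `-` are normalized on ingest by flipping both strands.

# Coordinate dialects

All internal coordinates are forward-strand half-open. The only
transformation used at format boundaries is

```
forward_start = size − (reverse_start + span)
```

applied to MAF minus-strand rows and to Chain minus-strand query
headers. PAF needs none. Because a single identity (an involution) does
all strand work, round trips through any format cannot drift by one
base without a test catching it.

# Conversion semantics

**To Chain.** Contiguous `=XM` runs merge into one gapless-block
`size`; a maximal run of gap operations between two blocks becomes one
`(dt, dq)` pair (`D` bases into `dt`, `I` bases into `dq` — the chain
grammar does not order the two within a gap line). Chains cannot
represent indels at the alignment edges, so leading/trailing `I`/`D`
runs are folded into the interval endpoints first, with a logged count;
the same trim runs on MAF and PAF emission so the three outputs stay
mutually consistent. The chain `score` is not defined by any spec we
follow; we emit the residue-match count when the cigar distinguishes
`=`/`X` and the aligned-column count otherwise — deterministic and
documented, with no claim of parity with other tools. Chain ids are
assigned sequentially from 1 in input order.

**From Chain.** Blocks become `M` runs and gaps become `D`/`I` runs;
with a store, texts are reconstructed and the cigar re-derived, which
resolves `M`. `chainToAlignment` is the exact inverse of
`alignmentToChain` up to that resolution.

**Residue matches in PAF.** Column 10 counts `=` bases plus unresolved
`M` bases, column 11 all aligned columns; both are recomputed from the
cigar on every emission, never copied.

# Indexing and extraction

The MAF index stores, per block, the byte offset of its `a` line plus
the target interval, sorted by start, serialized as a JSON sidecar for
transparency. The staleness fingerprint is the file's byte size — cheap
and sufficient to catch the realistic failure (file rewritten); content
hashing would be stronger but is not needed for correctness, because a
stale index is refused, not silently used. Extraction seeks directly to
offsets; equivalence with a brute-force scan over the whole file is the
tested property.

Trim mode keeps the columns whose target coordinate lies in the region.
Insertion (target-gap) columns attach to the *preceding* kept column,
and a leading insertion before the first kept column is dropped: this is
the only assignment that keeps the trimmed block's target interval
exactly inside the requested region. Row starts are recomputed by
counting consumed characters before the cut, which is strand-safe
because MAF starts are strand-relative and texts are stored in strand
order.

# Statistics, coverage, pseudo-MAF

`blastIdentity` is matches over aligned columns.
`gapCompressedIdentity` uses indel *events* (runs), not bases, in the
denominator — the convention that stops one long indel from swamping
identity. Coverage is the size of the union of target intervals
(IRanges reduction), checked against a per-base bitmap oracle.

The pseudo-MAF projects every query onto reference coordinates: one
reference-length row per query, with the aligned base at covered
positions, `x` where the alignment deletes the reference base, and `-`
where no block covers the position. The `x`/`-` distinction matters
because divergence must separate "aligned as deleted" (gap divergence)
from "not aligned at all" (coverage); insertions relative to the
reference are dropped, the price of keeping rows reference-length (a
union-gap MSA is out of scope). When two blocks of one query overlap a
position, the longer block wins and the conflict is logged. Divergence
rates are computed over covered positions only; a fully uncovered row
reports rates of 0 alongside `covered = 0` rather than NaN, so
downstream tabulation never propagates missingness silently.

# Variant calling

Each `X` column yields one SNP (MNP merging is deliberately off —
per-column records compose exactly with the truth sets). `I`/`D` runs
become left-anchored, VCF-style indels: REF/ALT start with the target
base immediately left of the run, so alleles are never empty. No
left-alignment beyond the anchor is attempted — the input alignment
defines placement. A run at the alignment start has no anchor; it is
skipped and tallied rather than emitted in a nonstandard form. Runs of
at least `svThreshold` bases (default 50 bp, the common SV convention)
carry `SVTYPE`/`SVLEN`.

Inversions use the strand signature: a minus-strand record flanked on
both sides by plus-strand records of the same query/target pair emits
one `<INV>` spanning its target interval. This is a heuristic — a lone
minus-strand record is ambiguous (could be a trans arrangement) and
produces no call.

The calling module is self-validating: `applyVariants` edits the target
subsequence with the calls and must reproduce the query subsequence
exactly. That reconstruction oracle runs over every sequence-bearing
record in the test suite.

# The synthetic generator

`generatePair` is first-class, tested code, not a test fixture: it
produces a uniform-random ACGT reference, a query built by applying
planted SNPs, insertions, deletions and optionally one inverted
segment, the truth MAF the construction implies, and the truth variant
list in the calling module's own conventions. Events are placed by
rejection sampling, pairwise ≥ 2 bp apart (so runs never merge and
bookkeeping stays exact), never at the alignment edges, never
overlapping the inversion; the inversion appears in the truth MAF as a
`+`,`−`,`+` block triple so inversion calling has a well-defined
target. The SNP alternate base is drawn uniformly from the three
non-reference bases. Identical seeds give byte-identical files; the
global RNG state is restored on exit.

What the generator does *not* emulate — repeats, microhomology at
breakpoints, realistic mutation-rate heterogeneity, sequencing error —
bounds what green tests mean: they certify the format algebra,
coordinate arithmetic and signature extraction, not aligner behaviour
on biological repeats.

# Problem sizes and numerical choices

The validation sweeps use 1 kb genome pairs (200 seeds) for the
round-trip and reconstruction properties, 10 kb targets with 500 blocks
and 100 random regions for the extraction oracle, and 100 random
interval sets for the coverage oracle — sizes chosen so the whole suite
exercises every path in seconds while the counts (hundreds of
independent random cases) make a silent one-off coordinate error
essentially impossible to miss. All quantities compared are integers or
exact rationals; no tolerance-based comparison is used anywhere, which
is the point of building conversion on integer CIGAR algebra.

Degenerate inputs have defined behaviour throughout: empty files read
to empty lists, an empty call set writes a header-only VCF, a region on
an absent chromosome extracts zero blocks (not an error), a one-block
file split into five chunks writes one file.

# Known limitations

* Pairwise only: MAF blocks with more than two rows are accepted by the
  reader but refused by converters.
* No random access into gzip-compressed MAF; compressed input is
  streamed, the byte-offset index applies to uncompressed files.
* Inversion calling is heuristic (flanked-strand signature only);
  duplications and translocations are not called.
* Chain `score` and edge-indel handling are this package's documented
  choices, not a reverse-engineered match of any other tool.
* Sequence sizes are R integers, capping sequences at 2^31−1 bp —
  ample for chromosomes, checked at construction.
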