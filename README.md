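# wgakit

Toolkit for pairwise **whole-genome alignments** (WGA): lossless
conversion among the three formats the field actually exchanges — MAF,
PAF and UCSC Chain — plus MAF indexing/extraction/splitting, alignment
statistics and filtering, reference coverage, pseudo-MAF projection with
SNP/gap divergence, alignment-signature variant calling to VCF, and
static dot-plot / terminal-style visualization. A deterministic synthetic
genome-pair generator with planted mutations and truth sets makes every
operation end-to-end testable.

It is written for comparative and population genomicists who align whole
assemblies (minimap2, wfmash, AnchorWave, ...) and then fight the format
zoo: MAF carries full gapped sequence text but no compact encoding, PAF
carries a CIGAR but no sequence, Chain carries gapless-block structure
and neither. Tools downstream each want a different one.

## The model

Every converter passes through one canonical, format-independent record.
A pairwise alignment is

* query and target names, sizes, and 0-based half-open intervals on the
  **forward** strand of both sequences,
* a strand `+`/`-` giving the query's orientation against the (always
  forward) target,
* a normalized **CIGAR** over the five-op alphabet `= X M I D`
  (match / mismatch / unresolved match-or-mismatch / insertion consuming
  query only / deletion consuming target only),
* optionally the two gapped alignment rows.

The CIGAR is the lossless core: MAF rows are compressed into it by a
column walk (`=` where bases agree, `X` where both present and differ,
`I`/`D` at gaps), Chain gapless blocks expand from it
(runs of `=XM` merge to a block `size`, `D` runs to `dt`, `I` runs to
`dq`), and PAF carries it verbatim in the `cg:Z:` tag. Strand dialects
are normalized at the format boundary with the single identity
`forward_start = size − (reverse_start + span)` (MAF and Chain count
minus-strand starts on the reverse-complemented sequence; PAF is always
forward). When a destination needs sequence text that the source lacks
(e.g. PAF → MAF), it is reconstructed from FASTA through a
`SequenceStore`, which also resolves `M` runs into `=`/`X`.

Variant calling reads alignment signatures directly: each `X` column is
a SNP, each `I`/`D` run one left-anchored insertion/deletion in VCF
style, runs ≥ 50 bp additionally annotated `SVTYPE`/`SVLEN`, and a
minus-strand record flanked by plus-strand records of the same query is
reported as an inversion.

## Worked example

Target `ACGTACGTAC` against query `ACGTTC-TAC` (one mismatch, one
deleted base):

```r
library(wgakit)
b <- MafBlock(data.frame(
  src = c("ref.chr1", "qry.chr1"), start = 0L, size = c(10L, 9L),
  strand = "+", srcSize = c(10L, 9L),
  text = c("ACGTACGTAC", "ACGTTC-TAC")))
a <- mafToAlignment(b)
a
#> AlignmentRecord: qry.chr1:0-9 (+, len 9) vs ref.chr1:0-10 (len 10)
#>   cigar: 4=1X1=1D3=
#>   texts: present
```

The 10 alignment columns classify as 8 matches, 1 mismatch and a 1 bp
deletion, so both identities are 0.8 (BLAST identity = matches/columns;
gap-compressed identity = matches/(matches + mismatches + gap events) =
8/(8+1+1)):

```r
recordStats(a)[, c("alignedColumns","matches","mismatches",
                   "blastIdentity","gapCompressedIdentity")]
#>   alignedColumns matches mismatches blastIdentity gapCompressedIdentity
#> 1             10       8          1           0.8                   0.8

writePaf(list(alignmentToPaf(a)), "-")
#> qry.chr1  9  0  9  +  ref.chr1  10  0  10  8  10  255  cg:Z:4=1X1=1D3=

writeChain(list(alignmentToChain(a, 1L)), "-")
#> chain 8 ref.chr1 10 + 0 10 qry.chr1 9 + 0 9 1
#> 6  1  0
#> 3
```

(residue matches 8, block length 10; the chain merges `4=1X1=` into a
6 bp block with a 1 bp target gap, then the final 3 bp block). The same
record yields exactly two variants — the SNP at position 5 and the
left-anchored deletion at position 6:

```r
writeVcf(callVariants(a), c(ref.chr1 = 10L), "-", provenance = FALSE)
#> ...
#> ref.chr1  5  .  A   T  .  PASS  .
#> ref.chr1  6  .  CG  C  .  PASS  .
```

## Command line

A thin launcher over the same functions lives at `inst/cli/wgakit.R`
(after installation: `system.file("cli", "wgakit.R", package = "wgakit")`):

```sh
Rscript wgakit.R synth --length 1000 --snps 20 --ins 8,60 --dels 5,55 --seed 42 --out-prefix pair
Rscript wgakit.R maf2paf pair.truth.maf pair.paf
Rscript wgakit.R paf2chain pair.paf pair.chain
Rscript wgakit.R chain2maf --target-fasta pair.ref.fa --query-fasta pair.qry.fa pair.chain back.maf
Rscript wgakit.R call pair.truth.maf calls.vcf
Rscript wgakit.R stat pair.truth.maf -
```

`-` means stdin/stdout, gzip input is auto-detected, and exit codes are
0 (success), 1 (usage error), 2 (format error naming file and line).

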