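Package: wgakit
Title: Manipulate Pairwise Whole-Genome Alignments in MAF, PAF and Chain Formats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A toolkit for pairwise whole-genome alignments (WGA). Provides
    lossless conversion among the MAF, PAF and UCSC Chain formats through a
    canonical alignment record built on a normalized CIGAR algebra; byte-offset
    indexing, interval-precise extraction and chunked splitting of MAF files;
    per-record alignment statistics, filtering, reference coverage, pseudo-MAF
    projection and SNP/gap divergence; alignment-signature variant calling
    (SNPs, insertions, deletions, inversions) to VCF; static dot-plot (SVG and
    segment TSV) and terminal-style block rendering; and a deterministic
    synthetic genome-pair generator with planted mutations and truth sets for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
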