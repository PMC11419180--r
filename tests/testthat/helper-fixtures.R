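# Shared fixtures and independent oracles, all built in code.

unrowname <- function(df) { rownames(df) <- NULL; df }

# The worked toy alignment: target ACGTACGTAC vs query ACGTTC-TAC.
toyBlock <- function() {
  MafBlock(data.frame(
    src = c("ref.chr1", "qry.chr1"), start = c(0L, 0L),
    size = c(10L, 9L), strand = c("+", "+"), srcSize = c(10L, 9L),
    text = c("ACGTACGTAC", "ACGTTC-TAC"), stringsAsFactors = FALSE))
}

toyAlignment <- function() mafToAlignment(toyBlock())

toyStore <- function() {
  SequenceStore(c(ref.chr1 = "ACGTACGTAC", qry.chr1 = "ACGTTCTAC"))
}

# Independent column-walk oracle: classify each column of two gapped rows.
oracleColumnOps <- function(targetText, queryText) {
  t <- strsplit(toupper(targetText), "")[[1L]]
  q <- strsplit(toupper(queryText), "")[[1L]]
  ifelse(t == "-", "I",
  ifelse(q == "-", "D",
  ifelse(t == q & t != "N", "=", "X")))
}

# Random normalized cigar for property tests.
randomCigar <- function(seed, maxRuns = 12L) {
  set.seed(seed)
  n <- sample.int(maxRuns, 1L)
  ops <- character(0)
  prev <- ""
  for (i in seq_len(n)) {
    op <- sample(setdiff(c("=", "X", "M", "I", "D"), prev), 1L)
    ops <- c(ops, op)
    prev <- op
  }
  Cigar(ops, sample.int(20L, n, replace = TRUE))
}

# Per-base bitmap coverage oracle over 0-based half-open intervals.
bitmapCovered <- function(starts, ends, len) {
  hit <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) hit[(starts[i] + 1L):ends[i]] <- TRUE
  }
  sum(hit)
}

# Minimal pure-match record covering a target interval (for coverage tests).
matchRecord <- function(tname, tsize, start, end,
                        qname = paste0("q.", start)) {
  span <- end - start
  AlignmentRecord(qname, span, 0L, span, "+", tname, tsize, start, end,
                  Cigar(sprintf("%d=", span)))
}

# Deterministic mutation load derived from a seed (the study conditions for
# the round-trip sweeps): a handful of SNPs and short indels in a 1 kb pair,
# every fifth seed also planting a 40 bp inversion.
roundtripPair <- function(seed) {
  set.seed(seed * 1000L + 7L)
  generatePair(1000L,
               nSnps = 3L + seed %% 8L,
               insertions = sample.int(12L, 2L),
               deletions = sample.int(12L, 2L),
               inversion = if (seed %% 5L == 0L) 40L else NULL,
               seed = seed)
}

# A 500-block MAF on a 10 kb target: identity blocks at random intervals.
manyBlockMaf <- function(path, nBlocks = 500L, tsize = 10000L, seed = 11L) {
  set.seed(seed)
  ref <- paste(sample(c("A", "C", "G", "T"), tsize, replace = TRUE),
               collapse = "")
  starts <- sample.int(tsize - 60L, nBlocks, replace = TRUE) - 1L
  spans <- sample(5:50, nBlocks, replace = TRUE)
  blocks <- lapply(seq_len(nBlocks), function(i) {
    s <- starts[i]; e <- s + spans[i]
    seg <- substr(ref, s + 1L, e)
    MafBlock(data.frame(
      src = c("ref.chr1", sprintf("qry.b%d", i)),
      start = c(s, 0L), size = spans[i], strand = "+",
      srcSize = c(tsize, spans[i]), text = c(seg, seg),
      stringsAsFactors = FALSE))
  })
  writeMaf(blocks, path)
  blocks
}
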