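test_that("mafToAlignment derives cigar and forward coordinates", {
  a <- toyAlignment()
  expect_equal(queryName(a), "qry.chr1")
  expect_equal(c(queryStart(a), queryEnd(a)), c(0L, 9L))
  expect_equal(c(targetStart(a), targetEnd(a)), c(0L, 10L))
  expect_equal(alnStrand(a), "+")
  expect_equal(cigarString(alnCigar(a)), "4=1X1=1D3=")

  # minus-strand query start is reverse-complement-relative:
  # start 2, span 5 on a 9 bp query -> forward [2, 7)
  b <- MafBlock(data.frame(
    src = c("ref.chr1", "qry.chr1"), start = c(0L, 2L), size = c(5L, 5L),
    strand = c("+", "-"), srcSize = c(10L, 9L),
    text = c("AAAAA", "AAAAA"), stringsAsFactors = FALSE))
  a2 <- mafToAlignment(b)
  expect_equal(c(queryStart(a2), queryEnd(a2)), c(2L, 7L))
  expect_equal(alnStrand(a2), "-")

  # identity block
  b3 <- MafBlock(data.frame(
    src = c("t", "q"), start = 0L, size = 4L, strand = "+", srcSize = 4L,
    text = "ACGT", stringsAsFactors = FALSE))
  expect_equal(cigarString(alnCigar(mafToAlignment(b3))), "4=")
})

test_that("alignmentToPaf fills the 12 columns from cigar stats", {
  p <- alignmentToPaf(toyAlignment())
  expect_equal(p@nMatch, 8L)
  expect_equal(p@blockLen, 10L)
  expect_equal(p@qEnd - p@qStart, 9L)
  expect_equal(p@tEnd - p@tStart, 10L)
  expect_equal(pafTag(p, "cg"), "4=1X1=1D3=")
  expect_equal(p@mapq, 255L)

  pure <- matchRecord("t", 100L, 10L, 30L)
  pp <- alignmentToPaf(pure)
  expect_equal(pp@nMatch, 20L)
  expect_equal(pp@blockLen, 20L)
})

test_that("pafToAlignment reconstructs texts from FASTA and rejects bad cg", {
  p <- alignmentToPaf(toyAlignment())
  a <- pafToAlignment(p, toyStore())
  expect_equal(targetText(a), "ACGTACGTAC")
  expect_equal(queryText(a), "ACGTTC-TAC")
  expect_equal(cigarString(cigarFromTexts(targetText(a), queryText(a))),
               cigarString(alnCigar(a)))

  # without a store the record converts with texts absent
  a0 <- pafToAlignment(p)
  expect_false(hasTexts(a0))

  noCg <- PafRecord("q", 9, 0, 9, "+", "t", 10, 0, 10, 8, 10)
  expect_error(pafToAlignment(noCg), class = "wga_skip")
  expect_error(PafRecord("q", 9, 0, 8, "+", "t", 10, 0, 10, 8, 10,
                         tags = "cg:Z:4=1X1=1D3="),
               regexp = "query-consumed")
})

test_that("alignmentToChain merges runs per the chain grammar", {
  ch <- alignmentToChain(toyAlignment(), 1L)
  expect_equal(unname(ch@blocks[, "size"]), c(6L, 3L))
  expect_equal(unname(ch@blocks[, "dt"]), c(1L, 0L))
  expect_equal(unname(ch@blocks[, "dq"]), c(0L, 0L))
  expect_true(validObject(ch))

  one <- alignmentToChain(matchRecord("t", 100L, 0L, 10L), 1L)
  expect_equal(nrow(one@blocks), 1)
  expect_equal(unname(one@blocks[1, ]), c(10L, 0L, 0L))

  # adjacent I then D collapse into one gap line
  a <- AlignmentRecord("q", 12L, 0L, 12L, "+", "t", 13L, 0L, 13L,
                       Cigar("5=2I3D5="))
  ch2 <- alignmentToChain(a, 2L)
  expect_equal(unname(ch2@blocks[, "size"]), c(5L, 5L))
  expect_equal(unname(ch2@blocks[, "dt"]), c(3L, 0L))
  expect_equal(unname(ch2@blocks[, "dq"]), c(2L, 0L))
})

test_that("chainToAlignment inverts the run merge, resolving M with FASTA", {
  ch <- alignmentToChain(toyAlignment(), 1L)
  a <- chainToAlignment(ch)
  expect_equal(cigarString(alnCigar(a)), "6M1D3M")
  aRes <- chainToAlignment(ch, toyStore())
  expect_equal(cigarString(alnCigar(aRes)), "4=1X1=1D3=")

  single <- ChainRecord(10, "t", 20, "+", 0, 10, "q", 10, "+", 0, 10, 1,
                        cbind(10L, 0L, 0L))
  expect_equal(cigarString(alnCigar(chainToAlignment(single))), "10M")
})

test_that("minus-strand chain coordinates are reverse-complement-relative", {
  g <- generatePair(600L, nSnps = 2L, inversion = 50L, seed = 13L)
  inv <- Filter(function(a) alnStrand(a) == "-", g$records)[[1]]
  ch <- alignmentToChain(inv, 3L)
  expect_equal(ch@qStrand, "-")
  expect_equal(ch@qStart, querySize(inv) - queryEnd(inv))
  expect_equal(ch@qEnd, querySize(inv) - queryStart(inv))
  back <- chainToAlignment(ch, g$store)
  expect_equal(queryStart(back), queryStart(inv))
  expect_equal(queryEnd(back), queryEnd(inv))
  expect_equal(cigarString(alnCigar(back)), cigarString(alnCigar(inv)))
})

test_that("alignment-edge indels are folded into the interval endpoints", {
  a <- AlignmentRecord("q", 20L, 0L, 15L, "+", "t", 20L, 0L, 13L,
                       Cigar("2I5=3D5=3I"),
                       queryText = "AACCGTA---CCGTAGGG",
                       targetText = "--CCGTATTTCCGTA---")
  expect_message(ch <- alignmentToChain(a, 1L), "trimmed")
  expect_equal(ch@tStart, 0L); expect_equal(ch@tEnd, 13L)
  expect_equal(ch@qStart, 2L); expect_equal(ch@qEnd, 12L)
  expect_true(validObject(ch))
  expect_message(p <- alignmentToPaf(a), "trimmed")
  expect_equal(pafTag(p, "cg"), "5=3D5=")
})

test_that("alignmentToMaf writes the strand-relative dialect and round-trips", {
  b <- toyBlock()
  expect_equal(alignmentToMaf(mafToAlignment(b))@rows, b@rows)
  expect_error(alignmentToMaf(matchRecord("t", 10L, 0L, 5L)),
               class = "wga_usage_error", regexp = "sequence required")

  g <- generatePair(600L, nSnps = 2L, inversion = 50L, seed = 13L)
  inv <- Filter(function(a) alnStrand(a) == "-", g$records)[[1]]
  m <- alignmentToMaf(inv)
  expect_equal(m@rows$strand[2], "-")
  expect_equal(m@rows$start[2], querySize(inv) - queryEnd(inv))
})

test_that("conversion conserves cigar totals across all six paths", {
  g <- generatePair(500L, nSnps = 6L, insertions = c(4L, 9L),
                    deletions = c(2L, 7L), seed = 21L)
  a <- g$records[[1]]
  base <- cigarStats(alnCigar(a))
  viaPaf <- pafToAlignment(alignmentToPaf(a), g$store)
  viaChain <- chainToAlignment(alignmentToChain(a, 1L), g$store)
  viaChainM <- chainToAlignment(alignmentToChain(a, 1L))
  for (x in list(viaPaf, viaChain)) {
    st <- cigarStats(alnCigar(x))
    expect_equal(st, base)
  }
  stM <- cigarStats(alnCigar(viaChainM))
  expect_equal(stM$matches + stM$mismatches + stM$ambiguous,
               base$matches + base$mismatches + base$ambiguous)
  expect_equal(stM$insBases, base$insBases)
  expect_equal(stM$delBases, base$delBases)
})
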