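test_that("recordStats computes identities per the expansion oracle", {
  st <- recordStats(toyAlignment())
  expect_equal(st$alignedColumns, 10)
  expect_equal(st$matches, 8)
  expect_equal(st$mismatches, 1)
  expect_equal(c(st$delEvents, st$delBases), c(1, 1))
  expect_equal(st$blastIdentity, 0.8)
  expect_equal(st$gapCompressedIdentity, 8 / 10)

  pure <- matchRecord("t", 50L, 0L, 20L)
  stp <- recordStats(pure)
  expect_equal(stp$blastIdentity, 1)
  expect_equal(stp$gapCompressedIdentity, 1)

  mm <- AlignmentRecord("q", 1L, 0L, 1L, "+", "t", 1L, 0L, 1L, Cigar("1X"))
  expect_equal(recordStats(mm)$blastIdentity, 0)
  expect_equal(recordStats(mm)$gapCompressedIdentity, 0)
})

test_that("recordStats totals reconcile with cigarStats for random records", {
  for (seed in 1:10) {
    cg <- randomCigar(seed)
    qc <- queryConsumed(cg); tc <- targetConsumed(cg)
    if (qc == 0 || tc == 0) next
    a <- AlignmentRecord("q", qc, 0L, qc, "+", "t", tc, 0L, tc, cg)
    st <- recordStats(a)
    cs <- cigarStats(cg)
    for (col in names(cs)) expect_equal(st[[col]], cs[[col]])
  }
})

test_that("filterRecords keeps by span, size and name with a reason tally", {
  a <- toyAlignment()  # target span 10, query size 9
  res <- filterRecords(list(a), minBlockLength = 11L)
  expect_length(res$kept, 0)
  expect_equal(unname(res$tally["short_block"]), 1L)

  res0 <- filterRecords(list(a))
  expect_length(res0$kept, 1)
  expect_equal(sum(res0$tally), 0L)

  three <- list(
    matchRecord("t", 100L, 0L, 5L, "qry.a"),        # short block
    matchRecord("t", 100L, 0L, 50L, "qry.b"),       # short query (size 50)
    matchRecord("t", 100L, 0L, 80L, "other.c"))     # name mismatch
  res3 <- filterRecords(three, minBlockLength = 10L, minQuerySize = 60L,
                        nameRegex = "^qry")
  expect_length(res3$kept, 0)
  expect_equal(sum(res3$tally), 3L)
  expect_equal(unname(res3$tally), c(1L, 1L, 1L))
  expect_error(filterRecords(three, nameRegex = "("),
               class = "wga_usage_error")
})

test_that("coverage equals the per-base bitmap oracle", {
  mk <- function(ints, tsize = 100L)
    lapply(seq_len(nrow(ints)), function(i)
      matchRecord("t", tsize, ints[i, 1], ints[i, 2]))
  cov <- alignmentCoverage(mk(rbind(c(0L, 10L), c(5L, 20L))))
  expect_equal(cov$covered, 20)
  expect_equal(cov$fraction, 0.2)
  cov2 <- alignmentCoverage(mk(rbind(c(0L, 10L), c(20L, 30L))))
  expect_equal(cov2$covered, 20)

  set.seed(42)
  for (i in 1:15) {
    k <- sample.int(12L, 1L)
    starts <- sample.int(900L, k) - 1L
    ends <- starts + sample.int(80L, k, replace = TRUE)
    recs <- lapply(seq_len(k), function(j)
      matchRecord("t", 1000L, starts[j], ends[j]))
    expect_equal(alignmentCoverage(recs)$covered,
                 bitmapCovered(starts, ends, 1000L))
  }
  expect_error(
    alignmentCoverage(list(matchRecord("t", 100L, 0L, 5L),
                           matchRecord("t", 200L, 0L, 5L))),
    class = "wga_format_error")
})

test_that("pseudo-MAF projects queries onto reference coordinates", {
  a <- toyAlignment()
  ps <- buildPseudoMaf(toyStore(), list(a), Region("ref.chr1", 0L, 10L))
  expect_equal(ps$ref, "ACGTACGTAC")
  expect_equal(unname(ps$rows["qry.chr1"]), "ACGTTCxTAC")
  expect_equal(nchar(ps$rows[[1]]), 10)

  # a query with no blocks in the region would simply be absent; a second
  # query contributes its own reference-length row
  b2 <- MafBlock(data.frame(
    src = c("ref.chr1", "qry2.chr1"), start = c(2L, 0L), size = 3L,
    strand = "+", srcSize = c(10L, 3L), text = c("GTA", "GTA"),
    stringsAsFactors = FALSE))
  ps2 <- buildPseudoMaf(toyStore(), list(a, mafToAlignment(b2)),
                        Region("ref.chr1", 0L, 10L))
  expect_equal(length(ps2$rows), 2)
  expect_true(all(nchar(ps2$rows) == 10))
  expect_equal(unname(ps2$rows["qry2.chr1"]), "--GTA-----")
})

test_that("divergence rates count SNP and gap cells over covered positions", {
  a <- toyAlignment()
  ps <- buildPseudoMaf(toyStore(), list(a), Region("ref.chr1", 0L, 10L))
  dv <- divergence(ps)
  expect_equal(dv$covered, 10)
  expect_equal(dv$snpRate, 1 / 10)
  expect_equal(dv$gapRate, 1 / 10)
  expect_equal(dv$coveredFraction, 1)

  ident <- MafBlock(data.frame(
    src = c("ref.chr1", "same"), start = 0L, size = 10L, strand = "+",
    srcSize = 10L, text = "ACGTACGTAC", stringsAsFactors = FALSE))
  dvi <- divergence(buildPseudoMaf(toyStore(), list(mafToAlignment(ident)),
                                   Region("ref.chr1", 0L, 10L)))
  expect_equal(c(dvi$snpRate, dvi$gapRate, dvi$coveredFraction), c(0, 0, 1))

  # degenerate: fully uncovered row reports rates 0 with covered = 0
  empty <- list(region = Region("ref.chr1", 0L, 10L), ref = "ACGTACGTAC",
                rows = c(ghost = "----------"))
  dve <- divergence(empty)
  expect_equal(dve$covered, 0)
  expect_equal(c(dve$snpRate, dve$gapRate, dve$coveredFraction), c(0, 0, 0))
})

test_that("pseudo-MAF lets the longer block win on overlap", {
  short <- MafBlock(data.frame(
    src = c("ref.chr1", "q"), start = c(0L, 0L), size = 4L, strand = "+",
    srcSize = c(10L, 12L), text = c("ACGT", "TTTT"), stringsAsFactors = FALSE))
  long <- MafBlock(data.frame(
    src = c("ref.chr1", "q"), start = c(0L, 4L), size = 8L, strand = "+",
    srcSize = c(10L, 12L), text = c("ACGTACGT", "ACGTACGT"),
    stringsAsFactors = FALSE))
  expect_message(
    ps <- buildPseudoMaf(toyStore(),
                         list(mafToAlignment(short), mafToAlignment(long)),
                         Region("ref.chr1", 0L, 10L)),
    "longer block wins")
  expect_equal(substr(ps$rows[["q"]], 1, 8), "ACGTACGT")
})
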