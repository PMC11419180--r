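test_that("index entries match a naive byte-offset scan", {
  f <- withr::local_tempfile(fileext = ".maf")
  g1 <- generatePair(200L, nSnps = 2L, seed = 1L)
  g2 <- generatePair(200L, nSnps = 1L, seed = 2L)
  writeMaf(c(g1$blocks, g2$blocks), f)
  idx <- buildMafIndex(f, sidecar = FALSE)
  expect_equal(nrow(idx@entries), 2)
  # oracle: offsets of lines starting with 'a', found by cumulative bytes
  lines <- readLines(f)
  offsets <- c(0, cumsum(nchar(lines, type = "bytes") + 1L))
  aLines <- which(startsWith(lines, "a"))
  expect_setequal(idx@entries$offset, offsets[aLines])
  # the offsets really point at the blocks
  con <- file(f, "rb")
  on.exit(close(con))
  seek(con, idx@entries$offset[1])
  expect_true(startsWith(readLines(con, 1), "a"))
})

test_that("index is deterministic, sidecar round-trips, empty MAF indexes empty", {
  d <- withr::local_tempdir()
  f <- file.path(d, "x.maf")
  g <- generatePair(200L, nSnps = 2L, seed = 3L)
  writeMaf(g$blocks, f)
  buildMafIndex(f)
  expect_true(file.exists(paste0(f, ".index")))
  first <- readLines(paste0(f, ".index"))
  buildMafIndex(f)
  expect_identical(readLines(paste0(f, ".index")), first)
  idx <- readMafIndex(paste0(f, ".index"))
  expect_equal(idx@entries, buildMafIndex(f, sidecar = FALSE)@entries)

  empty <- file.path(d, "empty.maf")
  writeMaf(list(), empty)
  expect_equal(nrow(buildMafIndex(empty, sidecar = FALSE)@entries), 0)
})

test_that("block-mode extraction equals a brute-force overlap scan", {
  f <- withr::local_tempfile(fileext = ".maf")
  blocks <- manyBlockMaf(f, nBlocks = 120L, tsize = 5000L, seed = 4L)
  idx <- buildMafIndex(f, sidecar = FALSE)
  tstarts <- vapply(blocks, function(b) b@rows$start[1], integer(1))
  tends <- tstarts + vapply(blocks, function(b) b@rows$size[1], integer(1))
  set.seed(99)
  for (i in 1:25) {
    s <- sample.int(4900L, 1L) - 1L
    r <- Region("ref.chr1", s, s + sample.int(300L, 1L))
    got <- extractRegion(f, idx, r, "block")
    want <- blocks[tstarts < r@end & tends > r@start]
    # extraction returns blocks sorted by target start; sort the oracle too
    want <- want[order(vapply(want, function(b) b@rows$start[1], integer(1)))]
    expect_equal(lapply(got, function(b) b@rows),
                 lapply(want, function(b) b@rows))
  }
  expect_length(extractRegion(f, idx, Region("nope.chr9", 0L, 10L), "block"),
                0)
})

test_that("trim mode slices to the target interval with gap attachment", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeMaf(list(toyBlock()), f)
  idx <- buildMafIndex(f, sidecar = FALSE)
  # whole-target region returns the block unchanged
  whole <- extractRegion(f, idx, Region("ref.chr1", 0L, 10L), "trim")
  expect_equal(whole[[1]]@rows, toyBlock()@rows)
  # [4, 7): target columns ACG, query TC-, cigar 1X1=1D
  tr <- extractRegion(f, idx, Region("ref.chr1", 4L, 7L), "trim")
  expect_length(tr, 1)
  r <- tr[[1]]@rows
  expect_equal(r$text, c("ACG", "TC-"))
  expect_equal(r$start, c(4L, 4L))
  expect_equal(r$size, c(3L, 2L))
  expect_true(validObject(tr[[1]]))
  a <- mafToAlignment(tr[[1]])
  expect_equal(cigarString(alnCigar(a)), "1X1=1D")
  # insertion columns attach to the preceding kept column
  ins <- MafBlock(data.frame(
    src = c("ref.chr1", "q"), start = 0L, size = c(6L, 8L), strand = "+",
    srcSize = c(10L, 8L), text = c("AC--GTAC", "ACTTGTAC"),
    stringsAsFactors = FALSE))
  writeMaf(list(ins), f)
  idx <- buildMafIndex(f, sidecar = FALSE)
  tr2 <- extractRegion(f, idx, Region("ref.chr1", 0L, 2L), "trim")
  expect_equal(tr2[[1]]@rows$text, c("AC--", "ACTT"))
  tr3 <- extractRegion(f, idx, Region("ref.chr1", 2L, 4L), "trim")
  expect_equal(tr3[[1]]@rows$text, c("GT", "GT"))  # leading insertion dropped
})

test_that("stale index fingerprints are refused", {
  d <- withr::local_tempdir()
  f <- file.path(d, "x.maf")
  g <- generatePair(150L, nSnps = 1L, seed = 6L)
  writeMaf(g$blocks, f)
  idx <- buildMafIndex(f, sidecar = FALSE)
  writeMaf(c(g$blocks, g$blocks), f)
  expect_error(extractRegion(f, idx, Region("ref.chr1", 0L, 10L)),
               class = "wga_usage_error", regexp = "out of date")
})

test_that("splitMaf partitions blocks and conserves the sequence", {
  d <- withr::local_tempdir()
  f <- file.path(d, "x.maf")
  blocks <- manyBlockMaf(f, nBlocks = 10L, tsize = 2000L, seed = 7L)
  files <- splitMaf(f, maxBlocks = 4L, outPrefix = file.path(d, "c"))
  expect_length(files, 3)
  counts <- vapply(files, function(x) length(readMaf(x)), integer(1))
  expect_equal(unname(counts), c(4L, 4L, 2L))
  # concatenation re-reads to the same block sequence
  joined <- unlist(lapply(files, readMaf), recursive = FALSE)
  expect_equal(lapply(joined, function(b) b@rows),
               lapply(blocks, function(b) b@rows))
  # never more chunks than blocks
  one <- file.path(d, "one.maf")
  writeMaf(blocks[1], one)
  expect_length(splitMaf(one, chunkCount = 5L,
                         outPrefix = file.path(d, "o")), 1)
  expect_error(splitMaf(f, chunkCount = 0L), class = "wga_usage_error")
  expect_error(splitMaf(f), class = "wga_usage_error")
})
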