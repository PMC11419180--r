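test_that("MAF reader hand-parses a block per the format rules", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "",
               "a score=8",
               "s ref.chr1 0 10 + 10 ACGTACGTAC",
               "s qry.chr1 0 9 + 9 ACGTTC-TAC", ""), f)
  blocks <- readMaf(f)
  expect_length(blocks, 1)
  r <- blocks[[1]]@rows
  expect_equal(nrow(r), 2)
  expect_equal(r$size, c(10L, 9L))
  expect_equal(r$src, c("ref.chr1", "qry.chr1"))
  expect_equal(blocks[[1]]@score, 8)
})

test_that("MAF reader handles empty input, bad rows and short blocks", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(character(0), f)
  expect_length(readMaf(f), 0)

  writeLines(c("a", "s ref 0 5 + 10 ACGTA", ""), f)  # one-row block
  expect_warning(blocks <- readMaf(f), "skipped")
  expect_length(blocks, 0)

  writeLines(c("a", "s ref 0 6 + 10 ACGTA", "s q 0 5 + 5 ACGTA"), f)
  expect_error(readMaf(f), class = "wga_format_error", regexp = "line 2")
})

test_that("MAF write/read round trip is stable", {
  g <- generatePair(300L, nSnps = 3L, insertions = 4L, seed = 5L)
  f <- withr::local_tempfile(fileext = ".maf")
  writeMaf(g$blocks, f)
  back <- readMaf(f)
  expect_equal(lapply(back, function(b) b@rows),
               lapply(g$blocks, function(b) b@rows))
  # write(read(write(x))) is byte-identical to write(x)
  f2 <- withr::local_tempfile(fileext = ".maf")
  writeMaf(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("PAF reader parses the 12 columns and keeps tags verbatim", {
  f <- withr::local_tempfile(fileext = ".paf")
  line <- "qry.chr1\t9\t0\t9\t+\tref.chr1\t10\t0\t10\t8\t10\t255\tcg:Z:4=1X1=1D3=\tzz:A:x"
  writeLines(line, f)
  p <- readPaf(f)[[1]]
  expect_equal(p@nMatch, 8L)
  expect_equal(p@blockLen, 10L)
  expect_equal(pafTag(p, "cg"), "4=1X1=1D3=")
  # consistency with cigar_stats
  st <- cigarStats(Cigar(pafTag(p, "cg")))
  expect_equal(st$matches, p@nMatch)
  expect_equal(st$alignedColumns, p@blockLen)
  # round trip preserves unknown tags in order
  f2 <- withr::local_tempfile(fileext = ".paf")
  writePaf(list(p), f2)
  expect_identical(readLines(f2), line)
})

test_that("PAF reader rejects malformed lines with the line number", {
  f <- withr::local_tempfile(fileext = ".paf")
  writeLines("q\t9\t0\t9\t+\tt\t10\t0\t10\t8\t10", f)  # 11 columns
  expect_error(readPaf(f), class = "wga_format_error", regexp = "line 1")
  writeLines("q\t9\t0\tx\t+\tt\t10\t0\t10\t8\t10\t255", f)
  expect_error(readPaf(f), class = "wga_format_error")
  writeLines("q\t9\t0\t9\t+\tt\t10\t0\t10\t8\t10\t255\tcg:Z:4=1P", f)
  expect_error(readPaf(f), class = "wga_format_error", regexp = "cg")
})

test_that("chain reader verifies the arithmetic invariants", {
  f <- withr::local_tempfile(fileext = ".chain")
  writeLines(c("chain 8 ref.chr1 10 + 0 10 qry.chr1 9 + 0 9 1",
               "6\t1\t0", "3", ""), f)
  ch <- readChain(f)[[1]]
  expect_equal(nrow(ch@blocks), 2)
  expect_equal(sum(ch@blocks[, "size"]), 9)
  expect_equal(sum(ch@blocks[, "dt"]), 1)
  expect_equal(sum(ch@blocks[, "dq"]), 0)
  # round trip byte-stable
  f2 <- withr::local_tempfile(fileext = ".chain")
  writeChain(readChain(f), f2)
  expect_identical(readLines(f2), readLines(f))

  writeLines(c("chain 8 ref.chr1 10 + 0 10 qry.chr1 9 + 0 8 1",
               "6\t1\t0", "3", ""), f)  # sum(size)+sum(dq) != qEnd-qStart
  expect_error(readChain(f), class = "wga_format_error")
  writeLines(c("chain 8 ref.chr1 10 + 0 10 qry.chr1 9 + 0 9 1",
               "6\t1\t0", "3\t0\t0", ""), f)  # final line must be size-only
  expect_error(readChain(f), class = "wga_format_error")
})

test_that("gzip-compressed inputs are accepted by all readers", {
  d <- withr::local_tempdir()
  g <- generatePair(200L, nSnps = 2L, seed = 8L)
  mafGz <- file.path(d, "x.maf.gz")
  con <- gzfile(mafGz, "wt")
  writeLines(c("##maf version=1", "",
               unlist(lapply(g$blocks, wgakit:::mafBlockLines))), con)
  close(con)
  expect_length(readMaf(mafGz), length(g$blocks))

  pafGz <- file.path(d, "x.paf.gz")
  con <- gzfile(pafGz, "wt")
  writeLines(wgakit:::pafLine(alignmentToPaf(g$records[[1]])), con)
  close(con)
  expect_length(readPaf(pafGz), 1)
})

test_that("VCF writer emits a parseable v4.2 file and enforces sort order", {
  a <- toyAlignment()
  calls <- callVariants(a)
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVcf(calls, c(ref.chr1 = 10L), f)
  lines <- readLines(f)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_true(any(grepl("##contig=<ID=ref.chr1,length=10>", lines, fixed = TRUE)))
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2)
  expect_equal(strsplit(body[1], "\t")[[1]][1:5],
               c("ref.chr1", "5", ".", "A", "T"))
  back <- readVcfCalls(f)
  expect_equal(back[, c("contig", "pos", "ref", "alt")],
               calls[, c("contig", "pos", "ref", "alt")])
  # header-only file for an empty call set
  writeVcf(calls[0, ], c(ref.chr1 = 10L), f)
  expect_true(all(startsWith(readLines(f), "#")))
  expect_error(writeVcf(calls[2:1, ], c(ref.chr1 = 10L), f),
               class = "wga_usage_error")
})

test_that("SequenceStore fetches strand-aware slices", {
  store <- SequenceStore(c(chr1 = "ACGTACGTAC"))
  expect_equal(fetchSeq(store, "chr1", 0, 4), "ACGT")
  expect_equal(fetchSeq(store, "chr1", 0, 4, "-"), "ACGT")
  expect_equal(fetchSeq(store, "chr1", 1, 5, "-"), "TACG")  # revcomp(CGTA)
  # reverse complement is an involution
  s <- fetchSeq(store, "chr1", 1, 9)
  expect_equal(wgakit:::revcompStr(wgakit:::revcompStr(s)), s)
  expect_error(fetchSeq(store, "chr2", 0, 1), class = "wga_fetch_error")
  expect_error(fetchSeq(store, "chr1", 0, 99), class = "wga_fetch_error")
})
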