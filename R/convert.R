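# Hub-and-spoke conversion among MAF, PAF and Chain through AlignmentRecord.
# All coordinate dialects are normalized here: MAF and Chain minus-strand
# starts are reverse-complement-relative (forward_start = size - (start +
# span)); PAF and the internal model are forward-strand half-open.

fwdStart <- function(start, span, strand, size) {
  if (strand == "+") start else size - (start + span)
}

#' Convert a pairwise MAF block to the canonical model
#'
#' Row 1 is taken as the target/reference, row 2 as the query. The cigar is
#' derived by the column walk over the gapped texts. A minus-strand target
#' row is normalized by flipping both strands so the target is forward.
#'
#' @param b a \linkS4class{MafBlock} with exactly 2 rows.
#' @return an \linkS4class{AlignmentRecord} with texts retained.
#' @export
mafToAlignment <- function(b) {
  r <- b@rows
  if (nrow(r) != 2L)
    wgaFormatError("conversion requires a pairwise block, found %d rows",
                   nrow(r))
  tRow <- r[1L, ]; qRow <- r[2L, ]
  if (tRow$strand == "-") {
    warning("minus-strand target row normalized to forward", call. = FALSE)
    tRow$text <- revcompStr(tRow$text)
    qRow$text <- revcompStr(qRow$text)
    tRow$start <- tRow$srcSize - (tRow$start + tRow$size)
    qRow$start <- qRow$srcSize - (qRow$start + qRow$size)
    tRow$strand <- "+"
    qRow$strand <- if (qRow$strand == "+") "-" else "+"
  }
  qStartFwd <- fwdStart(qRow$start, qRow$size, qRow$strand, qRow$srcSize)
  AlignmentRecord(
    queryName = qRow$src, querySize = qRow$srcSize,
    queryStart = qStartFwd, queryEnd = qStartFwd + qRow$size,
    strand = qRow$strand,
    targetName = tRow$src, targetSize = tRow$srcSize,
    targetStart = tRow$start, targetEnd = tRow$start + tRow$size,
    cigar = cigarFromTexts(tRow$text, qRow$text),
    queryText = qRow$text, targetText = tRow$text)
}

# Drop leading/trailing I/D runs, folding them into the interval endpoints.
# Chain cannot represent alignment-edge indels; the same trim is applied on
# every emission path so the three formats stay mutually consistent.
trimEdgeIndels <- function(a) {
  ops <- a@cigar@ops; lens <- a@cigar@lengths
  tStart <- a@targetStart; tEnd <- a@targetEnd
  qStart <- a@queryStart; qEnd <- a@queryEnd
  tText <- a@targetText; qText <- a@queryText
  trimmed <- 0L
  while (length(ops) && ops[1L] %in% c("I", "D")) {
    len <- lens[1L]
    if (ops[1L] == "D") {
      tStart <- tStart + len
    } else if (a@strand == "+") {
      qStart <- qStart + len
    } else {
      qEnd <- qEnd - len
    }
    if (!is.na(tText)) tText <- substr(tText, len + 1L, nchar(tText))
    if (!is.na(qText)) qText <- substr(qText, len + 1L, nchar(qText))
    ops <- ops[-1L]; lens <- lens[-1L]; trimmed <- trimmed + 1L
  }
  while (length(ops) && ops[length(ops)] %in% c("I", "D")) {
    n <- length(ops); len <- lens[n]
    if (ops[n] == "D") {
      tEnd <- tEnd - len
    } else if (a@strand == "+") {
      qEnd <- qEnd - len
    } else {
      qStart <- qStart + len
    }
    if (!is.na(tText)) tText <- substr(tText, 1L, nchar(tText) - len)
    if (!is.na(qText)) qText <- substr(qText, 1L, nchar(qText) - len)
    ops <- ops[-n]; lens <- lens[-n]; trimmed <- trimmed + 1L
  }
  if (trimmed == 0L) return(a)
  message(sprintf("trimmed %d alignment-edge indel run(s) into the interval",
                  trimmed))
  AlignmentRecord(a@queryName, a@querySize, qStart, qEnd, a@strand,
                  a@targetName, a@targetSize, tStart, tEnd,
                  new("Cigar", ops = ops, lengths = lens), qText, tText)
}

#' Convert the canonical model to a PAF record
#'
#' Residue matches count \code{=} bases plus unresolved \code{M} bases; the
#' block length is the number of aligned columns. The cigar is emitted as a
#' \code{cg:Z:} tag. Missing mapping quality is written as 255.
#'
#' @param a an \linkS4class{AlignmentRecord}.
#' @return a \linkS4class{PafRecord}.
#' @export
alignmentToPaf <- function(a) {
  a <- trimEdgeIndels(a)
  st <- cigarStats(a@cigar)
  PafRecord(a@queryName, a@querySize, a@queryStart, a@queryEnd, a@strand,
            a@targetName, a@targetSize, a@targetStart, a@targetEnd,
            nMatch = st$matches + st$ambiguous, blockLen = st$alignedColumns,
            mapq = 255L,
            tags = paste0("cg:Z:", cigarString(a@cigar)))
}

#' Convert a PAF record to the canonical model
#'
#' Requires the \code{cg} tag (records without it cannot be converted
#' losslessly and raise a skip condition the CLI tallies). With a
#' \code{\link{SequenceStore}}, the gapped texts are reconstructed by
#' walking the cigar over the fetched subsequences; the query slice is
#' reverse-complemented for minus-strand records.
#'
#' @param p a \linkS4class{PafRecord}.
#' @param store optional \code{\link{SequenceStore}} holding both sequences.
#' @return an \linkS4class{AlignmentRecord}.
#' @export
pafToAlignment <- function(p, store = NULL) {
  cg <- pafTag(p, "cg")
  if (is.na(cg))
    stop(errorCondition(
      sprintf("PAF record %s vs %s has no cg tag; skipped", p@qName, p@tName),
      class = c("wga_skip", "wga_error")))
  a <- AlignmentRecord(p@qName, p@qLen, p@qStart, p@qEnd, p@strand,
                       p@tName, p@tLen, p@tStart, p@tEnd, Cigar(cg))
  if (!is.null(store)) a <- reconstructTexts(a, store)
  a
}

#' Rebuild gapped alignment texts from a SequenceStore
#'
#' Walks the cigar over the fetched target and query subsequences, inserting
#' gap characters at I/D runs, and resolves any \code{M} runs into
#' \code{=}/\code{X} against the actual bases.
#'
#' @param a an \linkS4class{AlignmentRecord} (texts may be absent).
#' @param store a \code{\link{SequenceStore}}.
#' @return the record with texts present and cigar fully resolved.
#' @export
reconstructTexts <- function(a, store) {
  tSeq <- fetchSeq(store, a@targetName, a@targetStart, a@targetEnd, "+")
  qSeq <- fetchSeq(store, a@queryName, a@queryStart, a@queryEnd, a@strand)
  ops <- a@cigar@ops; lens <- a@cigar@lengths
  tParts <- character(length(ops)); qParts <- character(length(ops))
  tPos <- 0L; qPos <- 0L
  for (i in seq_along(ops)) {
    len <- lens[i]
    if (ops[i] %in% c("=", "X", "M")) {
      tParts[i] <- substr(tSeq, tPos + 1L, tPos + len)
      qParts[i] <- substr(qSeq, qPos + 1L, qPos + len)
      tPos <- tPos + len; qPos <- qPos + len
    } else if (ops[i] == "I") {
      tParts[i] <- strrep("-", len)
      qParts[i] <- substr(qSeq, qPos + 1L, qPos + len)
      qPos <- qPos + len
    } else {
      tParts[i] <- substr(tSeq, tPos + 1L, tPos + len)
      qParts[i] <- strrep("-", len)
      tPos <- tPos + len
    }
  }
  tText <- paste(tParts, collapse = "")
  qText <- paste(qParts, collapse = "")
  a@targetText <- tText
  a@queryText <- qText
  a@cigar <- cigarFromTexts(tText, qText)  # resolves M into =/X
  validObject(a)
  a
}

#' Convert the canonical model to a chain record
#'
#' Contiguous \code{=}/\code{X}/\code{M} runs merge into one gapless block
#' \code{size}; contiguous gap runs contribute \code{dt} (deletions) and
#' \code{dq} (insertions) of a single gap line. Alignment-edge indels are
#' folded into the header intervals first (the chain grammar cannot carry
#' them). Minus-strand query coordinates are rewritten to the
#' reverse-complement-relative chain dialect. The score is the residue-match
#' count when the cigar distinguishes matches, else the aligned-column count.
#'
#' @param a an \linkS4class{AlignmentRecord}.
#' @param chainId chain id to stamp on the record.
#' @return a \linkS4class{ChainRecord}.
#' @export
alignmentToChain <- function(a, chainId = 1L) {
  a <- trimEdgeIndels(a)
  ops <- a@cigar@ops; lens <- a@cigar@lengths
  if (!length(ops))
    wgaFormatError("cannot emit an empty alignment as a chain")
  sizes <- integer(0); dts <- integer(0); dqs <- integer(0)
  curSize <- 0L; curDt <- 0L; curDq <- 0L; inGap <- FALSE
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("=", "X", "M")) {
      if (inGap) {  # close the previous (size, dt, dq) line
        sizes <- c(sizes, curSize); dts <- c(dts, curDt); dqs <- c(dqs, curDq)
        curSize <- 0L; curDt <- 0L; curDq <- 0L; inGap <- FALSE
      }
      curSize <- curSize + lens[i]
    } else {
      inGap <- TRUE
      if (ops[i] == "D") curDt <- curDt + lens[i] else curDq <- curDq + lens[i]
    }
  }
  sizes <- c(sizes, curSize); dts <- c(dts, 0L); dqs <- c(dqs, 0L)
  st <- cigarStats(a@cigar)
  score <- if (any(ops %in% c("=", "X"))) st$matches else st$alignedColumns
  if (a@strand == "-") {
    qs <- a@querySize - a@queryEnd
    qe <- a@querySize - a@queryStart
  } else {
    qs <- a@queryStart; qe <- a@queryEnd
  }
  ChainRecord(score, a@targetName, a@targetSize, "+", a@targetStart,
              a@targetEnd, a@queryName, a@querySize, a@strand, qs, qe,
              chainId, cbind(sizes, dts, dqs))
}

#' Convert a chain record to the canonical model
#'
#' Without sequence the gapless blocks become \code{M} runs (losslessly
#' invertible); with a \code{\link{SequenceStore}} the texts are
#' reconstructed and \code{M} resolves into \code{=}/\code{X}.
#'
#' @param cr a \linkS4class{ChainRecord}.
#' @param store optional \code{\link{SequenceStore}}.
#' @return an \linkS4class{AlignmentRecord}.
#' @export
chainToAlignment <- function(cr, store = NULL) {
  b <- cr@blocks
  ops <- character(0); lens <- integer(0)
  for (i in seq_len(nrow(b))) {
    ops <- c(ops, "M"); lens <- c(lens, b[i, 1L])
    if (b[i, 2L] > 0L) { ops <- c(ops, "D"); lens <- c(lens, b[i, 2L]) }
    if (b[i, 3L] > 0L) { ops <- c(ops, "I"); lens <- c(lens, b[i, 3L]) }
  }
  if (cr@qStrand == "-") {
    qs <- cr@qSize - cr@qEnd
    qe <- cr@qSize - cr@qStart
  } else {
    qs <- cr@qStart; qe <- cr@qEnd
  }
  a <- AlignmentRecord(cr@qName, cr@qSize, qs, qe, cr@qStrand,
                       cr@tName, cr@tSize, cr@tStart, cr@tEnd,
                       Cigar(ops, lens))
  if (!is.null(store)) a <- reconstructTexts(a, store)
  a
}

#' Convert the canonical model to a pairwise MAF block
#'
#' The target row comes first; minus-strand query starts are rewritten to
#' the strand-relative MAF dialect. Texts are taken from the record or
#' reconstructed from a \code{\link{SequenceStore}}.
#'
#' @param a an \linkS4class{AlignmentRecord}.
#' @param store optional \code{\link{SequenceStore}} used when texts are
#'   absent.
#' @param score optional score for the \code{a} line.
#' @return a \linkS4class{MafBlock}.
#' @export
alignmentToMaf <- function(a, store = NULL, score = NA_real_) {
  a <- trimEdgeIndels(a)
  if (!hasTexts(a)) {
    if (is.null(store))
      wgaUsageError("sequence required: record has no texts and no store given")
    a <- reconstructTexts(a, store)
  }
  qSpan <- a@queryEnd - a@queryStart
  qStartMaf <- if (a@strand == "+") a@queryStart else
    a@querySize - a@queryEnd
  MafBlock(data.frame(
    src = c(a@targetName, a@queryName),
    start = c(a@targetStart, qStartMaf),
    size = c(a@targetEnd - a@targetStart, qSpan),
    strand = c("+", a@strand),
    srcSize = c(a@targetSize, a@querySize),
    text = c(a@targetText, a@queryText),
    stringsAsFactors = FALSE), score = score)
}
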