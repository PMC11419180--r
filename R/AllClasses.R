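CIGAR_OPS <- c("=", "X", "M", "I", "D")
QUERY_CONSUMING <- c("=", "X", "M", "I")
TARGET_CONSUMING <- c("=", "X", "M", "D")

#' Cigar: run-length encoded alignment operations
#'
#' A normalized CIGAR holds an ordered sequence of runs, each a kind from the
#' five-letter alphabet \code{=} (match), \code{X} (mismatch), \code{M}
#' (ambiguous match/mismatch), \code{I} (insertion, consumes query only) and
#' \code{D} (deletion, consumes target only), with a positive run length in
#' bases. Normalization means no two consecutive runs share a kind.
#'
#' @slot ops character vector of run kinds.
#' @slot lengths integer vector of run lengths, parallel to \code{ops}.
#' @name Cigar-class
#' @aliases Cigar-class
#' @exportClass Cigar
setClass("Cigar", representation(ops = "character", lengths = "integer"))

setValidity("Cigar", function(object) {
  msgs <- character(0)
  if (length(object@ops) != length(object@lengths))
    msgs <- c(msgs, "ops and lengths must have equal length")
  bad <- setdiff(unique(object@ops), CIGAR_OPS)
  if (length(bad))
    msgs <- c(msgs, paste0("illegal CIGAR op(s): ", paste(bad, collapse = ", ")))
  if (length(object@lengths) && any(is.na(object@lengths) | object@lengths < 1L))
    msgs <- c(msgs, "all run lengths must be >= 1")
  n <- length(object@ops)
  if (n > 1L && any(object@ops[-1L] == object@ops[-n]))
    msgs <- c(msgs, "not normalized: consecutive runs share a kind")
  if (length(msgs)) msgs else TRUE
})

#' AlignmentRecord: canonical pairwise alignment
#'
#' The format-independent hub through which all conversions pass. Coordinates
#' are 0-based half-open on the forward strand of both sequences; \code{strand}
#' gives the orientation of the query relative to the (always forward) target.
#' Gapped aligned sequence rows are optional (\code{NA} when absent); when both
#' are present they must reproduce the cigar column-for-column.
#'
#' @slot queryName,targetName sequence identifiers.
#' @slot querySize,targetSize total sequence lengths in bp.
#' @slot queryStart,queryEnd,targetStart,targetEnd 0-based half-open intervals,
#'   forward strand.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot cigar a \linkS4class{Cigar}.
#' @slot queryText,targetText gapped aligned rows (uppercase bases and
#'   \code{"-"}), or \code{NA_character_}.
#' @name AlignmentRecord-class
#' @aliases AlignmentRecord-class
#' @exportClass AlignmentRecord
setClass("AlignmentRecord", representation(
  queryName = "character", querySize = "integer",
  queryStart = "integer", queryEnd = "integer",
  strand = "character",
  targetName = "character", targetSize = "integer",
  targetStart = "integer", targetEnd = "integer",
  cigar = "Cigar",
  queryText = "character", targetText = "character"
))

setValidity("AlignmentRecord", function(object) {
  msgs <- character(0)
  if (!object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  qc <- queryConsumed(object@cigar)
  tc <- targetConsumed(object@cigar)
  if (object@queryEnd - object@queryStart != qc)
    msgs <- c(msgs, sprintf(
      "query interval width %d != query-consumed cigar bases %d",
      object@queryEnd - object@queryStart, qc))
  if (object@targetEnd - object@targetStart != tc)
    msgs <- c(msgs, sprintf(
      "target interval width %d != target-consumed cigar bases %d",
      object@targetEnd - object@targetStart, tc))
  if (object@queryStart < 0L || object@queryStart > object@queryEnd ||
      object@queryEnd > object@querySize)
    msgs <- c(msgs, "query interval out of bounds")
  if (object@targetStart < 0L || object@targetStart > object@targetEnd ||
      object@targetEnd > object@targetSize)
    msgs <- c(msgs, "target interval out of bounds")
  qt <- object@queryText; tt <- object@targetText
  if (!is.na(qt) && !is.na(tt)) {
    if (nchar(qt) != nchar(tt))
      msgs <- c(msgs, "aligned text rows differ in length")
    else {
      if (nchar(gsub("-", "", qt, fixed = TRUE)) != qc)
        msgs <- c(msgs, "ungapped query text length != query-consumed bases")
      if (nchar(gsub("-", "", tt, fixed = TRUE)) != tc)
        msgs <- c(msgs, "ungapped target text length != target-consumed bases")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Region: a named half-open interval
#'
#' @slot name sequence identifier.
#' @slot start,end 0-based half-open interval, \code{start < end}.
#' @name Region-class
#' @aliases Region-class
#' @exportClass Region
setClass("Region", representation(name = "character", start = "integer",
                                  end = "integer"))

setValidity("Region", function(object) {
  if (object@start < 0L || object@start >= object@end)
    "need 0 <= start < end" else TRUE
})

#' MafBlock: one MAF alignment block
#'
#' Rows are held in a data.frame with columns \code{src}, \code{start},
#' \code{size}, \code{strand}, \code{srcSize}, \code{text}. By the pairwise
#' convention used throughout, row 1 is the target/reference and row 2 the
#' query. MAF starts are strand-relative: on a \code{-} row the start is
#' counted on the reverse-complemented sequence.
#'
#' @slot score numeric score from the \code{a} line (\code{NA} when absent).
#' @slot rows data.frame of \code{s} rows in file order.
#' @name MafBlock-class
#' @aliases MafBlock-class
#' @exportClass MafBlock
setClass("MafBlock", representation(score = "numeric", rows = "data.frame"))

setValidity("MafBlock", function(object) {
  msgs <- character(0)
  r <- object@rows
  need <- c("src", "start", "size", "strand", "srcSize", "text")
  if (!all(need %in% names(r)))
    return(paste("rows must have columns", paste(need, collapse = ", ")))
  if (nrow(r) < 2L) msgs <- c(msgs, "a block needs at least 2 rows")
  ungap <- nchar(gsub("-", "", r$text, fixed = TRUE))
  if (any(ungap != r$size))
    msgs <- c(msgs, "ungapped text length != declared size")
  if (any(r$start < 0L) || any(r$start + r$size > r$srcSize))
    msgs <- c(msgs, "row interval out of sequence bounds")
  if (!all(r$strand %in% c("+", "-")))
    msgs <- c(msgs, "row strand must be '+' or '-'")
  if (length(msgs)) msgs else TRUE
})

#' PafRecord: one PAF line
#'
#' The 12 mandatory columns plus optional typed tags, kept verbatim in input
#' order so round trips are byte-stable. Query coordinates are always on the
#' forward strand, per the PAF convention.
#'
#' @slot qName,tName sequence names.
#' @slot qLen,qStart,qEnd,tLen,tStart,tEnd integer coordinates (0-based
#'   half-open).
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot nMatch residue matches; \code{blockLen} alignment block length;
#'   \code{mapq} mapping quality (255 = missing).
#' @slot tags character vector of full \code{tag:type:value} strings.
#' @name PafRecord-class
#' @aliases PafRecord-class
#' @exportClass PafRecord
setClass("PafRecord", representation(
  qName = "character", qLen = "integer", qStart = "integer", qEnd = "integer",
  strand = "character",
  tName = "character", tLen = "integer", tStart = "integer", tEnd = "integer",
  nMatch = "integer", blockLen = "integer", mapq = "integer",
  tags = "character"
))

setValidity("PafRecord", function(object) {
  msgs <- character(0)
  if (!(object@qStart >= 0L && object@qStart < object@qEnd &&
        object@qEnd <= object@qLen))
    msgs <- c(msgs, "query interval violates 0 <= qstart < qend <= qlen")
  if (!(object@tStart >= 0L && object@tStart < object@tEnd &&
        object@tEnd <= object@tLen))
    msgs <- c(msgs, "target interval violates 0 <= tstart < tend <= tlen")
  if (!object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (object@nMatch > object@blockLen)
    msgs <- c(msgs, "residue matches exceed block length")
  cg <- pafTag(object, "cg")
  if (!is.na(cg)) {
    c <- Cigar(cg)
    if (queryConsumed(c) != object@qEnd - object@qStart)
      msgs <- c(msgs, "cg query-consumed bases != qend - qstart")
    if (targetConsumed(c) != object@tEnd - object@tStart)
      msgs <- c(msgs, "cg target-consumed bases != tend - tstart")
  }
  if (length(msgs)) msgs else TRUE
})

#' ChainRecord: one UCSC chain
#'
#' A header followed by gapless-block data lines \code{(size, dt, dq)}; the
#' final line carries \code{size} only (stored here with \code{dt = dq = 0}).
#' The target strand is always \code{+}; minus-strand query coordinates are
#' counted on the reverse-complemented query sequence, per the chain dialect.
#'
#' @slot score chain score.
#' @slot tName,tSize,tStrand,tStart,tEnd target header fields.
#' @slot qName,qSize,qStrand,qStart,qEnd query header fields.
#' @slot id chain id.
#' @slot blocks integer matrix with columns \code{size}, \code{dt}, \code{dq}.
#' @name ChainRecord-class
#' @aliases ChainRecord-class
#' @exportClass ChainRecord
setClass("ChainRecord", representation(
  score = "numeric",
  tName = "character", tSize = "integer", tStrand = "character",
  tStart = "integer", tEnd = "integer",
  qName = "character", qSize = "integer", qStrand = "character",
  qStart = "integer", qEnd = "integer",
  id = "integer", blocks = "matrix"
))

setValidity("ChainRecord", function(object) {
  msgs <- character(0)
  b <- object@blocks
  if (ncol(b) != 3L)
    return("blocks must be an n x 3 matrix (size, dt, dq)")
  if (object@tStrand != "+")
    msgs <- c(msgs, "target strand must be '+'")
  if (!object@qStrand %in% c("+", "-"))
    msgs <- c(msgs, "query strand must be '+' or '-'")
  if (nrow(b)) {
    if (any(b[, 1L] < 1L)) msgs <- c(msgs, "all block sizes must be >= 1")
    if (any(b[, 2:3] < 0L)) msgs <- c(msgs, "dt and dq must be >= 0")
    if (sum(b[, 1L]) + sum(b[, 2L]) != object@tEnd - object@tStart)
      msgs <- c(msgs, sprintf(
        "chain %d: sum(size) + sum(dt) != tEnd - tStart", object@id))
    if (sum(b[, 1L]) + sum(b[, 3L]) != object@qEnd - object@qStart)
      msgs <- c(msgs, sprintf(
        "chain %d: sum(size) + sum(dq) != qEnd - qStart", object@id))
  }
  if (length(msgs)) msgs else TRUE
})

#' MafIndex: byte-offset index of a MAF file by target coordinates
#'
#' One entry per block, keyed by the target (first) row: byte offset of the
#' block's \code{a} line plus the block's target interval. Entries are sorted
#' by (name, targetStart). The source file's byte size is recorded as a
#' staleness fingerprint.
#'
#' @slot entries data.frame with columns \code{name}, \code{offset},
#'   \code{targetStart}, \code{targetEnd}.
#' @slot fileSize byte size of the indexed file at build time.
#' @name MafIndex-class
#' @aliases MafIndex-class
#' @exportClass MafIndex
setClass("MafIndex", representation(entries = "data.frame",
                                    fileSize = "numeric"))
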