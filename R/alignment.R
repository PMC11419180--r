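# The canonical AlignmentRecord: constructor, accessors, show.

#' Construct an AlignmentRecord
#'
#' @param queryName,querySize,queryStart,queryEnd query side; coordinates
#'   0-based half-open on the forward strand.
#' @param strand orientation of the query relative to the target.
#' @param targetName,targetSize,targetStart,targetEnd target side (always
#'   forward).
#' @param cigar a \linkS4class{Cigar} or CIGAR string.
#' @param queryText,targetText optional gapped aligned rows.
#' @return an \linkS4class{AlignmentRecord}.
#' @export
AlignmentRecord <- function(queryName, querySize, queryStart, queryEnd,
                            strand, targetName, targetSize, targetStart,
                            targetEnd, cigar,
                            queryText = NA_character_,
                            targetText = NA_character_) {
  if (is.character(cigar)) cigar <- Cigar(cigar)
  new("AlignmentRecord",
      queryName = as.character(queryName), querySize = as.integer(querySize),
      queryStart = as.integer(queryStart), queryEnd = as.integer(queryEnd),
      strand = as.character(strand),
      targetName = as.character(targetName),
      targetSize = as.integer(targetSize),
      targetStart = as.integer(targetStart),
      targetEnd = as.integer(targetEnd),
      cigar = cigar,
      queryText = if (is.na(queryText)) NA_character_ else toupper(queryText),
      targetText = if (is.na(targetText)) NA_character_ else toupper(targetText))
}

#' @rdname AlignmentRecord
#' @param x an \linkS4class{AlignmentRecord}.
#' @export
queryName <- function(x) x@queryName
#' @rdname AlignmentRecord
#' @export
targetName <- function(x) x@targetName
#' @rdname AlignmentRecord
#' @export
querySize <- function(x) x@querySize
#' @rdname AlignmentRecord
#' @export
targetSize <- function(x) x@targetSize
#' @rdname AlignmentRecord
#' @export
queryStart <- function(x) x@queryStart
#' @rdname AlignmentRecord
#' @export
queryEnd <- function(x) x@queryEnd
#' @rdname AlignmentRecord
#' @export
targetStart <- function(x) x@targetStart
#' @rdname AlignmentRecord
#' @export
targetEnd <- function(x) x@targetEnd
#' @rdname AlignmentRecord
#' @export
alnStrand <- function(x) x@strand
#' @rdname AlignmentRecord
#' @export
alnCigar <- function(x) x@cigar
#' @rdname AlignmentRecord
#' @export
queryText <- function(x) x@queryText
#' @rdname AlignmentRecord
#' @export
targetText <- function(x) x@targetText

#' @rdname AlignmentRecord
#' @export
hasTexts <- function(x) !is.na(x@queryText) && !is.na(x@targetText)

setMethod("show", "AlignmentRecord", function(object) {
  cat(sprintf("AlignmentRecord: %s:%d-%d (%s, len %d) vs %s:%d-%d (len %d)\n",
              object@queryName, object@queryStart, object@queryEnd,
              object@strand, object@querySize,
              object@targetName, object@targetStart, object@targetEnd,
              object@targetSize))
  cs <- cigarString(object@cigar)
  if (nchar(cs) > 60L) cs <- paste0(substr(cs, 1L, 57L), "...")
  cat("  cigar:", cs, "\n")
  cat("  texts:", if (hasTexts(object)) "present" else "absent", "\n")
})
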