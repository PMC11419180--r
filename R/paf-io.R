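# PAF reader/writer: 12 mandatory tab-separated columns plus typed tags
# (notably cg:Z: carrying the CIGAR). Query intervals are forward-strand.

#' @rdname PafRecord-class
#' @param qName,qLen,qStart,qEnd,strand,tName,tLen,tStart,tEnd,nMatch,blockLen,mapq
#'   the 12 mandatory PAF columns.
#' @param tags character vector of \code{tag:type:value} strings, kept in
#'   order.
#' @export
PafRecord <- function(qName, qLen, qStart, qEnd, strand, tName, tLen, tStart,
                      tEnd, nMatch, blockLen, mapq = 255L,
                      tags = character(0)) {
  new("PafRecord", qName = as.character(qName), qLen = as.integer(qLen),
      qStart = as.integer(qStart), qEnd = as.integer(qEnd),
      strand = as.character(strand), tName = as.character(tName),
      tLen = as.integer(tLen), tStart = as.integer(tStart),
      tEnd = as.integer(tEnd), nMatch = as.integer(nMatch),
      blockLen = as.integer(blockLen), mapq = as.integer(mapq),
      tags = as.character(tags))
}

#' @rdname PafRecord-class
#' @param x a \linkS4class{PafRecord}.
#' @param tag two-letter tag name, e.g. \code{"cg"}.
#' @return \code{pafTag}: the tag's value string, or \code{NA} if absent.
#' @export
pafTag <- function(x, tag) {
  hit <- grep(paste0("^", tag, ":"), x@tags, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub("^..:.:", "", hit[1L])
}

setMethod("show", "PafRecord", function(object) {
  cat(sprintf("PafRecord: %s:%d-%d %s %s:%d-%d match %d / block %d\n",
              object@qName, object@qStart, object@qEnd, object@strand,
              object@tName, object@tStart, object@tEnd, object@nMatch,
              object@blockLen))
  if (length(object@tags))
    cat("  tags:", paste(sub(":.*", "", object@tags), collapse = " "), "\n")
})

parsePafLine <- function(line, lineno) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 12L)
    wgaFormatError("line %d: PAF needs >= 12 columns, found %d",
                   lineno, length(f))
  ints <- suppressWarnings(as.integer(f[c(2:4, 7:12)]))
  if (anyNA(ints))
    wgaFormatError("line %d: non-integer coordinate in PAF columns", lineno)
  tags <- if (length(f) > 12L) f[13:length(f)] else character(0)
  cg <- grep("^cg:", tags, value = TRUE)
  if (length(cg) && grepl("[^0-9=XMID]", sub("^cg:.:", "", cg[1L])))
    wgaFormatError("line %d: illegal op symbol in cg tag", lineno)
  PafRecord(f[1L], ints[1L], ints[2L], ints[3L], f[5L], f[6L],
            ints[4L], ints[5L], ints[6L], ints[7L], ints[8L],
            ints[9L], tags)
}

#' Read a PAF file
#'
#' Unknown tags are preserved verbatim, so write-back is byte-stable.
#' Accepts gzip input and \code{"-"} for standard input.
#'
#' @param path file path.
#' @return list of \linkS4class{PafRecord} in file order.
#' @export
readPaf <- function(path) {
  lines <- readAllLines(path)
  keep <- which(!grepl("^\\s*$", lines) & substr(lines, 1L, 1L) != "#")
  lapply(keep, function(i) parsePafLine(lines[[i]], i))
}

pafLine <- function(p) {
  paste(c(p@qName, p@qLen, p@qStart, p@qEnd, p@strand, p@tName, p@tLen,
          p@tStart, p@tEnd, p@nMatch, p@blockLen, p@mapq, p@tags),
        collapse = "\t")
}

#' Write a PAF file
#'
#' @param records list of \linkS4class{PafRecord}.
#' @param path output path (\code{"-"} for standard output).
#' @export
writePaf <- function(records, path) {
  writeAllLines(vapply(records, pafLine, character(1)), path)
}
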