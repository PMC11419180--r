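# UCSC chain reader/writer. A record is a "chain ..." header followed by
# data lines "size dt dq"; the last line carries size only. Minus-strand
# query coordinates are counted on the reverse-complemented sequence.

#' @rdname ChainRecord-class
#' @param score,tName,tSize,tStrand,tStart,tEnd,qName,qSize,qStrand,qStart,qEnd,id
#'   header fields.
#' @param blocks n x 3 matrix (or data.frame) of \code{size}, \code{dt},
#'   \code{dq}; the last row's \code{dt}/\code{dq} must be 0.
#' @export
ChainRecord <- function(score, tName, tSize, tStrand, tStart, tEnd,
                        qName, qSize, qStrand, qStart, qEnd, id, blocks) {
  blocks <- matrix(as.integer(as.matrix(blocks)), ncol = 3L,
                   dimnames = list(NULL, c("size", "dt", "dq")))
  new("ChainRecord", score = as.numeric(score),
      tName = as.character(tName), tSize = as.integer(tSize),
      tStrand = as.character(tStrand), tStart = as.integer(tStart),
      tEnd = as.integer(tEnd),
      qName = as.character(qName), qSize = as.integer(qSize),
      qStrand = as.character(qStrand), qStart = as.integer(qStart),
      qEnd = as.integer(qEnd), id = as.integer(id), blocks = blocks)
}

setMethod("show", "ChainRecord", function(object) {
  cat(sprintf("ChainRecord %d: %s:%d-%d -> %s(%s):%d-%d, %d block(s), score %g\n",
              object@id, object@tName, object@tStart, object@tEnd,
              object@qName, object@qStrand, object@qStart, object@qEnd,
              nrow(object@blocks), object@score))
})

#' Read a UCSC chain file
#'
#' Chain arithmetic (sum of sizes plus gaps equals the header spans) is
#' verified on every record; a violation is a format error citing the chain
#' id. Accepts gzip input and \code{"-"} for standard input.
#'
#' @param path file path.
#' @return list of \linkS4class{ChainRecord} in file order.
#' @export
readChain <- function(path) {
  lines <- readAllLines(path)
  records <- list()
  header <- NULL
  rows <- list()
  closed <- FALSE
  flush <- function() {
    if (is.null(header)) return()
    if (!closed)
      wgaFormatError("chain %s: final data line must carry size only",
                     header[13L])
    b <- do.call(rbind, rows)
    rec <- tryCatch(
      ChainRecord(as.numeric(header[2L]), header[3L], header[4L], header[5L],
                  header[6L], header[7L], header[8L], header[9L], header[10L],
                  header[11L], header[12L], header[13L], b),
      error = function(e) wgaFormatError("chain %s: %s", header[13L],
                                         conditionMessage(e)))
    records[[length(records) + 1L]] <<- rec
    header <<- NULL; rows <<- list(); closed <<- FALSE
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "" || substr(line, 1L, 1L) == "#") next
    f <- strsplit(line, "\\s+")[[1L]]
    if (f[1L] == "chain") {
      flush()
      if (length(f) != 13L)
        wgaFormatError("line %d: chain header needs 13 fields, found %d",
                       i, length(f))
      header <- f
    } else {
      if (is.null(header))
        wgaFormatError("line %d: data line outside any chain", i)
      if (closed)
        wgaFormatError("line %d: data after the final size-only line", i)
      v <- suppressWarnings(as.integer(f))
      if (anyNA(v))
        wgaFormatError("line %d: non-integer chain data", i)
      if (length(v) == 1L) {
        rows[[length(rows) + 1L]] <- c(v, 0L, 0L)
        closed <- TRUE
      } else if (length(v) == 3L) {
        rows[[length(rows) + 1L]] <- v
      } else {
        wgaFormatError("line %d: chain data line needs 1 or 3 fields", i)
      }
    }
  }
  flush()
  records
}

chainLines <- function(cr) {
  b <- cr@blocks
  n <- nrow(b)
  body <- if (n > 1L)
    sprintf("%d\t%d\t%d", b[-n, 1L], b[-n, 2L], b[-n, 3L]) else character(0)
  c(sprintf("chain %s %s %d %s %d %d %s %d %s %d %d %d",
            format(cr@score, scientific = FALSE), cr@tName, cr@tSize,
            cr@tStrand, cr@tStart, cr@tEnd, cr@qName, cr@qSize, cr@qStrand,
            cr@qStart, cr@qEnd, cr@id),
    body,
    as.character(b[n, 1L]),
    "")
}

#' Write a UCSC chain file
#'
#' Tab-separated data lines, records separated by a blank line.
#'
#' @param records list of \linkS4class{ChainRecord}.
#' @param path output path (\code{"-"} for standard output).
#' @export
writeChain <- function(records, path) {
  writeAllLines(unlist(lapply(records, chainLines), use.names = FALSE), path)
}
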