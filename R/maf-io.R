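# MAF reader/writer. Blocks start with an 'a' line, carry 's' sequence rows,
# and are separated by blank lines. Starts are strand-relative: a '-' row's
# start is counted on the reverse-complemented sequence.

#' @rdname MafBlock-class
#' @param rows data.frame of \code{s}-row fields (\code{src}, \code{start},
#'   \code{size}, \code{strand}, \code{srcSize}, \code{text}).
#' @param score optional numeric score for the \code{a} line.
#' @export
MafBlock <- function(rows, score = NA_real_) {
  rows$src <- as.character(rows$src)
  rows$start <- as.integer(rows$start)
  rows$size <- as.integer(rows$size)
  rows$strand <- as.character(rows$strand)
  rows$srcSize <- as.integer(rows$srcSize)
  rows$text <- toupper(as.character(rows$text))
  rownames(rows) <- NULL
  new("MafBlock", score = as.numeric(score), rows = rows)
}

setMethod("show", "MafBlock", function(object) {
  cat(sprintf("MafBlock: %d rows%s\n", nrow(object@rows),
              if (is.na(object@score)) "" else sprintf(", score %g",
                                                       object@score)))
  r <- object@rows
  for (i in seq_len(min(nrow(r), 4L))) {
    txt <- r$text[i]
    if (nchar(txt) > 40L) txt <- paste0(substr(txt, 1L, 37L), "...")
    cat(sprintf("  s %s %d %d %s %d %s\n", r$src[i], r$start[i], r$size[i],
                r$strand[i], r$srcSize[i], txt))
  }
})

parseMafLines <- function(lines, offsets = NULL) {
  blocks <- list()
  blockOffsets <- numeric(0)
  cur <- NULL   # list(score, rows, startLine, offset)
  flush <- function() {
    if (is.null(cur)) return()
    if (nrow(cur$rows) < 2L) {
      warning(sprintf("MAF block at line %d has %d row(s); skipped",
                      cur$startLine, nrow(cur$rows)), call. = FALSE)
    } else {
      blocks[[length(blocks) + 1L]] <<- MafBlock(cur$rows, cur$score)
      blockOffsets[length(blockOffsets) + 1L] <<- cur$offset
    }
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^\\s*$", line)) { flush(); next }
    first <- substr(line, 1L, 1L)
    if (first == "#") next
    if (first == "a") {
      flush()
      score <- NA_real_
      m <- regmatches(line, regexec("score=([-0-9.eE+]+)", line))[[1L]]
      if (length(m) == 2L) score <- as.numeric(m[2L])
      cur <- list(score = score,
                  rows = data.frame(src = character(0), start = integer(0),
                                    size = integer(0), strand = character(0),
                                    srcSize = integer(0), text = character(0),
                                    stringsAsFactors = FALSE),
                  startLine = i,
                  offset = if (is.null(offsets)) NA_real_ else offsets[i])
    } else if (first == "s") {
      if (is.null(cur))
        wgaFormatError("line %d: 's' row outside any block", i)
      f <- strsplit(trimws(line), "\\s+")[[1L]]
      if (length(f) != 7L)
        wgaFormatError("line %d: 's' row needs 7 fields, found %d",
                       i, length(f))
      start <- suppressWarnings(as.integer(f[3L]))
      size <- suppressWarnings(as.integer(f[4L]))
      srcSize <- suppressWarnings(as.integer(f[6L]))
      if (anyNA(c(start, size, srcSize)))
        wgaFormatError("line %d: non-integer coordinate in 's' row", i)
      if (nchar(ungap(f[7L])) != size)
        wgaFormatError(
          "line %d: declared size %d != ungapped text length %d",
          i, size, nchar(ungap(f[7L])))
      cur$rows[nrow(cur$rows) + 1L, ] <- list(f[2L], start, size, f[5L],
                                              srcSize, f[7L])
    }
    # other row types (i, e, q) are tolerated and ignored
  }
  flush()
  list(blocks = blocks, offsets = blockOffsets)
}

#' Read a MAF file
#'
#' Accepts plain or gzip-compressed input; \code{"-"} reads standard input.
#' Blocks with fewer than two \code{s} rows are skipped with a warning.
#'
#' @param path file path.
#' @return list of \linkS4class{MafBlock} in file order.
#' @export
readMaf <- function(path) {
  parseMafLines(readAllLines(path))$blocks
}

mafBlockLines <- function(b) {
  r <- b@rows
  c(if (is.na(b@score)) "a" else sprintf("a score=%s",
                                         format(b@score, scientific = FALSE)),
    sprintf("s %s %d %d %s %d %s", r$src, r$start, r$size, r$strand,
            r$srcSize, r$text),
    "")
}

#' Write a MAF file
#'
#' Normalized output: a \code{##maf} header, single-space-separated \code{s}
#' rows with uppercase text, blank line after every block.
#'
#' @param blocks list of \linkS4class{MafBlock}.
#' @param path output path (\code{"-"} for standard output).
#' @export
writeMaf <- function(blocks, path) {
  lines <- c("##maf version=1", "",
             unlist(lapply(blocks, mafBlockLines), use.names = FALSE))
  writeAllLines(lines, path)
}
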