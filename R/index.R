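# MAF indexing, interval-precise extraction, and chunked splitting.
# The index maps target-sequence name -> (byte offset of the block's 'a'
# line, target interval), sorted by target start, and is persisted as a JSON
# sidecar next to the MAF file.

#' @rdname MafIndex-class
#' @param entries data.frame with columns \code{name}, \code{offset},
#'   \code{targetStart}, \code{targetEnd}.
#' @param fileSize byte size of the indexed file.
#' @export
MafIndex <- function(entries, fileSize) {
  entries <- entries[order(entries$name, entries$targetStart), , drop = FALSE]
  rownames(entries) <- NULL
  new("MafIndex", entries = entries, fileSize = as.numeric(fileSize))
}

setMethod("show", "MafIndex", function(object) {
  cat(sprintf("MafIndex: %d block(s) on %d target sequence(s)\n",
              nrow(object@entries), length(unique(object@entries$name))))
})

#' Build a byte-offset index of a MAF file
#'
#' One entry per block, keyed by the target (first) row. The sidecar is
#' written next to the input with suffix \code{.index} (JSON). The file's
#' byte size is stored as a staleness fingerprint. Works on uncompressed
#' MAF only (byte offsets are meaningless inside gzip streams).
#'
#' @param path MAF file path.
#' @param sidecar write the \code{<path>.index} sidecar.
#' @return a \linkS4class{MafIndex}, invisibly when \code{sidecar} is TRUE.
#' @export
buildMafIndex <- function(path, sidecar = TRUE) {
  lines <- readLines(path, warn = FALSE)
  # offset of the start of line i, assuming '\n' terminators
  offsets <- c(0, cumsum(nchar(lines, type = "bytes") + 1L))[seq_along(lines)]
  parsed <- parseMafLines(lines, offsets)
  entries <- data.frame(name = character(0), offset = numeric(0),
                        targetStart = integer(0), targetEnd = integer(0),
                        stringsAsFactors = FALSE)
  for (i in seq_along(parsed$blocks)) {
    t <- parsed$blocks[[i]]@rows[1L, ]
    entries[nrow(entries) + 1L, ] <- list(t$src, parsed$offsets[i],
                                          t$start, t$start + t$size)
  }
  idx <- MafIndex(entries, file.size(path))
  if (sidecar) {
    writeMafIndex(idx, paste0(path, ".index"))
    return(invisible(idx))
  }
  idx
}

#' @rdname buildMafIndex
#' @param index a \linkS4class{MafIndex}.
#' @param indexPath sidecar path.
#' @export
writeMafIndex <- function(index, indexPath) {
  jsonlite::write_json(
    list(fileSize = index@fileSize, entries = index@entries),
    indexPath, auto_unbox = TRUE, digits = NA)
  invisible(indexPath)
}

#' @rdname buildMafIndex
#' @export
readMafIndex <- function(indexPath) {
  x <- jsonlite::read_json(indexPath, simplifyVector = TRUE)
  e <- x$entries
  if (length(e) == 0L || nrow(as.data.frame(e)) == 0L) {
    e <- data.frame(name = character(0), offset = numeric(0),
                    targetStart = integer(0), targetEnd = integer(0),
                    stringsAsFactors = FALSE)
  }
  MafIndex(as.data.frame(e), x$fileSize)
}

readBlockAt <- function(con, offset) {
  seek(con, offset)
  lines <- character(0)
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line) || grepl("^\\s*$", line)) break
    lines <- c(lines, line)
  }
  parseMafLines(lines)$blocks[[1L]]
}

#' Extract blocks overlapping a target region from an indexed MAF
#'
#' \code{mode = "block"} returns every block whose target interval overlaps
#' the region, whole. \code{mode = "trim"} additionally slices each block to
#' the alignment columns whose target coordinate lies inside the region;
#' insertion (target-gap) columns are attached to the preceding kept column,
#' and a leading insertion before the first kept column is dropped. Row
#' starts and sizes are recomputed so the returned blocks are valid.
#'
#' @param path MAF file path (uncompressed).
#' @param index a \linkS4class{MafIndex} for \code{path}.
#' @param region a \linkS4class{Region} (0-based half-open).
#' @param mode \code{"block"} or \code{"trim"}.
#' @return list of \linkS4class{MafBlock} (possibly empty).
#' @export
extractRegion <- function(path, index, region, mode = c("block", "trim")) {
  mode <- match.arg(mode)
  if (!isTRUE(all.equal(index@fileSize, file.size(path))))
    wgaUsageError("index out of date for '%s' (file size changed)", path)
  e <- index@entries[index@entries$name == region@name, , drop = FALSE]
  if (!nrow(e)) return(list())
  # entries are sorted by targetStart: bisect to the first candidate, then
  # scan while targetStart < region end, guarding with the running max end
  hit <- e[e$targetStart < region@end & e$targetEnd > region@start, ,
           drop = FALSE]
  if (!nrow(hit)) return(list())
  con <- file(path, "rb")
  on.exit(close(con))
  blocks <- lapply(hit$offset, function(off) readBlockAt(con, off))
  if (mode == "block") return(blocks)
  out <- lapply(blocks, trimBlockToRegion, region = region)
  out[!vapply(out, is.null, logical(1))]
}

# Slice one block to the target interval; NULL when nothing remains.
trimBlockToRegion <- function(b, region) {
  r <- b@rows
  if (r$strand[1L] != "+")
    wgaFormatError("trim requires a forward-strand target row")
  cols <- strsplit(r$text, "", fixed = TRUE)
  tcons <- cols[[1L]] != "-"
  tcoord <- rep(NA_integer_, length(tcons))
  tcoord[tcons] <- r$start[1L] + seq_len(sum(tcons)) - 1L
  keep <- which(tcons & tcoord >= region@start & tcoord < region@end)
  if (!length(keep)) return(NULL)
  first <- min(keep)
  last <- max(keep)
  while (last < length(tcons) && !tcons[last + 1L]) last <- last + 1L
  newRows <- r
  for (i in seq_len(nrow(r))) {
    chars <- cols[[i]]
    consumedBefore <- sum(chars[seq_len(first - 1L)] != "-")
    newText <- paste(chars[first:last], collapse = "")
    newRows$start[i] <- r$start[i] + consumedBefore
    newRows$size[i] <- nchar(ungap(newText))
    newRows$text[i] <- newText
  }
  if (any(newRows$size == 0L)) return(NULL)  # a row vanished entirely
  MafBlock(newRows, b@score)
}

#' Split a MAF file into sequential chunks
#'
#' Blocks are partitioned in file order, never split inside a block, into
#' either \code{chunkCount} chunks of near-equal block count or chunks of at
#' most \code{maxBlocks} blocks. No empty chunks are written; concatenating
#' the outputs re-reads to the input's block sequence.
#'
#' @param path MAF file path.
#' @param chunkCount number of chunks (mutually exclusive with
#'   \code{maxBlocks}).
#' @param maxBlocks maximum blocks per chunk.
#' @param outPrefix output prefix; chunk i is written to
#'   \code{<outPrefix>.<i>.maf}.
#' @return character vector of files written.
#' @export
splitMaf <- function(path, chunkCount = NULL, maxBlocks = NULL,
                     outPrefix = sub("\\.maf$", "", path)) {
  if (is.null(chunkCount) == is.null(maxBlocks))
    wgaUsageError("give exactly one of chunkCount or maxBlocks")
  blocks <- readMaf(path)
  n <- length(blocks)
  if (n == 0L) return(character(0))
  if (!is.null(chunkCount)) {
    if (chunkCount < 1L) wgaUsageError("chunkCount must be >= 1")
    per <- ceiling(n / min(chunkCount, n))
  } else {
    if (maxBlocks < 1L) wgaUsageError("maxBlocks must be >= 1")
    per <- maxBlocks
  }
  starts <- seq(1L, n, by = per)
  files <- character(0)
  for (i in seq_along(starts)) {
    sel <- starts[i]:min(starts[i] + per - 1L, n)
    f <- sprintf("%s.%d.maf", outPrefix, i)
    writeMaf(blocks[sel], f)
    files <- c(files, f)
  }
  files
}
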