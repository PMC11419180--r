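# Error conditions and small shared helpers.

#' Signal a format error
#'
#' Malformed input files raise conditions of class \code{wga_format_error} so
#' callers (and the CLI, which maps them to exit code 2) can distinguish them
#' from usage errors (\code{wga_usage_error}, exit code 1).
#'
#' @param fmt,... passed to \code{sprintf}.
#' @keywords internal
wgaFormatError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("wga_format_error", "wga_error")))
}

wgaUsageError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("wga_usage_error", "wga_error")))
}

#' Open a text input connection
#'
#' \code{"-"} means standard input. gzip-compressed files are decompressed
#' transparently (magic-byte detection by the connection layer).
#' @keywords internal
openInput <- function(path) {
  if (identical(path, "-")) return(stdin())
  if (!file.exists(path))
    stop(errorCondition(sprintf("cannot open '%s': no such file", path),
                        class = c("wga_io_error", "wga_error")))
  gzfile(path, "rt")
}

readAllLines <- function(path) {
  con <- openInput(path)
  if (!identical(path, "-")) on.exit(close(con))
  readLines(con, warn = FALSE)
}

writeAllLines <- function(lines, path) {
  if (identical(path, "-")) {
    writeLines(lines, stdout())
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' Reverse-complement a base string (IUPAC-aware, via Biostrings)
#' @keywords internal
revcompStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Parse a CLI region string
#'
#' Grammar \code{name:start-end}, 1-based inclusive as users write it, mapped
#' to the 0-based half-open \linkS4class{Region} used internally.
#'
#' @param x a string like \code{"chr1:100-200"}.
#' @return a \linkS4class{Region}.
#' @export
#' @examples
#' parseRegion("chr1:100-200")  # Region chr1:[99, 200)
parseRegion <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))[[1L]]
  if (length(m) != 4L)
    wgaUsageError("malformed region '%s' (expected name:start-end)", x)
  start1 <- as.integer(m[3L]); end1 <- as.integer(m[4L])
  if (start1 < 1L || end1 < start1)
    wgaUsageError("malformed region '%s': need 1 <= start <= end", x)
  Region(m[2L], start1 - 1L, end1)
}

#' @rdname Region-class
#' @param name sequence identifier.
#' @param start,end 0-based half-open interval.
#' @export
Region <- function(name, start, end) {
  new("Region", name = as.character(name), start = as.integer(start),
      end = as.integer(end))
}

setMethod("show", "Region", function(object) {
  cat(sprintf("Region %s:[%d, %d)\n", object@name, object@start, object@end))
})
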