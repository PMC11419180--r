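# Sequence access for conversions that must reconstruct alignment text.
# Thin wrapper over a Biostrings DNAStringSet with strand-aware fetching.

#' SequenceStore: in-memory FASTA access
#'
#' Builds a name -> sequence mapping from FASTA files (or an existing
#' \code{DNAStringSet} / named character vector). \code{fetchSeq} returns the
#' subsequence over a 0-based half-open interval, reverse-complemented when
#' \code{strand} is \code{"-"}.
#'
#' @param ... FASTA file paths, \code{DNAStringSet}s, or named character
#'   vectors; multiple sources are concatenated.
#' @return a \code{DNAStringSet} used as the store.
#' @export
#' @examples
#' store <- SequenceStore(c(chr1 = "ACGTACGTAC"))
#' fetchSeq(store, "chr1", 0, 4)         # "ACGT"
#' fetchSeq(store, "chr1", 0, 4, "-")    # "ACGT" reverse-complemented
SequenceStore <- function(...) {
  parts <- lapply(list(...), function(src) {
    if (is(src, "DNAStringSet")) return(src)
    if (is.character(src) && !is.null(names(src)))
      return(Biostrings::DNAStringSet(toupper(src)))
    if (is.character(src)) {
      missing <- src[!file.exists(src)]
      if (length(missing))
        stop(errorCondition(
          sprintf("FASTA file not found: %s", missing[1L]),
          class = c("wga_io_error", "wga_error")))
      return(Reduce(c, lapply(src, Biostrings::readDNAStringSet)))
    }
    stop("unsupported SequenceStore source")
  })
  out <- Reduce(c, parts)
  # FASTA headers may carry descriptions after the first token
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname SequenceStore
#' @param store a store built by \code{SequenceStore}.
#' @param name sequence name.
#' @param start,end 0-based half-open interval.
#' @param strand \code{"+"} or \code{"-"} (reverse-complement the slice).
#' @export
fetchSeq <- function(store, name, start, end, strand = "+") {
  if (!name %in% names(store))
    stop(errorCondition(sprintf("sequence '%s' not in store", name),
                        class = c("wga_fetch_error", "wga_error")))
  len <- length(store[[name]])
  if (start < 0L || end > len || start > end)
    stop(errorCondition(
      sprintf("interval [%d, %d) out of bounds for '%s' (length %d)",
              start, end, name, len),
      class = c("wga_fetch_error", "wga_error")))
  s <- Biostrings::subseq(store[[name]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
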