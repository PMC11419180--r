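# The CIGAR algebra shared by every conversion: parsing, normalization,
# expansion to columns, derivation from gapped texts, and summary statistics.

normalizeRuns <- function(ops, lengths) {
  keep <- lengths > 0L
  ops <- ops[keep]; lengths <- lengths[keep]
  if (length(ops) > 1L) {
    grp <- cumsum(c(TRUE, ops[-1L] != ops[-length(ops)]))
    lengths <- as.integer(tapply(lengths, grp, sum))
    ops <- ops[!duplicated(grp)]
    names(lengths) <- NULL
  }
  list(ops = ops, lengths = lengths)
}

#' Construct or parse a Cigar
#'
#' Accepts a CIGAR text like \code{"4=1X1=1D3="}, or parallel \code{ops} /
#' \code{lengths} vectors. Runs are normalized (adjacent same-kind runs
#' merged, zero-length runs dropped).
#'
#' @param x CIGAR string, or a character vector of op kinds when
#'   \code{lengths} is given.
#' @param lengths run lengths parallel to \code{x}.
#' @return a \linkS4class{Cigar}.
#' @export
#' @examples
#' Cigar("4=1X1=1D3=")
#' Cigar(c("=", "I", "="), c(2, 2, 2))
Cigar <- function(x, lengths = NULL) {
  if (is.null(lengths)) {
    stopifnot(is.character(x), length(x) == 1L)
    if (nchar(x) == 0L) {
      norm <- list(ops = character(0), lengths = integer(0))
    } else {
      m <- gregexpr("[0-9]+[=XMID]", x)[[1L]]
      runs <- regmatches(x, gregexpr("[0-9]+[=XMID]", x))[[1L]]
      if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(x))
        wgaFormatError("illegal CIGAR string '%s'", x)
      norm <- normalizeRuns(substr(runs, nchar(runs), nchar(runs)),
                            as.integer(substr(runs, 1L, nchar(runs) - 1L)))
    }
  } else {
    norm <- normalizeRuns(as.character(x), as.integer(lengths))
  }
  new("Cigar", ops = norm$ops, lengths = norm$lengths)
}

#' @describeIn Cigar render as CIGAR text.
#' @param cigar a \linkS4class{Cigar}.
#' @export
cigarString <- function(cigar) {
  paste0(cigar@lengths, cigar@ops, collapse = "")
}

#' @describeIn Cigar run kinds and lengths as a data.frame.
#' @export
cigarRuns <- function(cigar) {
  data.frame(op = cigar@ops, len = cigar@lengths, stringsAsFactors = FALSE)
}

#' @describeIn Cigar query bases consumed (kinds \code{= X M I}).
#' @export
queryConsumed <- function(cigar) {
  sum(cigar@lengths[cigar@ops %in% QUERY_CONSUMING])
}

#' @describeIn Cigar target bases consumed (kinds \code{= X M D}).
#' @export
targetConsumed <- function(cigar) {
  sum(cigar@lengths[cigar@ops %in% TARGET_CONSUMING])
}

#' @describeIn Cigar expand to one op symbol per alignment column.
#' @export
expandCigar <- function(cigar) {
  rep(cigar@ops, cigar@lengths)
}

setMethod("show", "Cigar", function(object) {
  cat("Cigar:", if (length(object@ops)) cigarString(object) else "<empty>",
      "\n")
})

#' Derive a Cigar from two gapped alignment rows
#'
#' Classifies every column of a pairwise alignment: \code{=} where the bases
#' agree (case-insensitively), \code{X} where both bases are present and
#' differ (a base against \code{N} counts as a mismatch), \code{I} where the
#' target row has a gap, \code{D} where the query row has a gap. MAF blocks
#' carry no CIGAR, so this column walk is how they enter the canonical model.
#'
#' @param targetText,queryText equal-length gapped rows over
#'   \code{A C G T N -}.
#' @return a normalized \linkS4class{Cigar}.
#' @export
#' @examples
#' cigarString(cigarFromTexts("ACGTACGTAC", "ACGTTC-TAC"))  # "4=1X1=1D3="
cigarFromTexts <- function(targetText, queryText) {
  if (nchar(targetText) == 0L || nchar(queryText) == 0L)
    wgaFormatError("empty alignment row")
  if (nchar(targetText) != nchar(queryText))
    wgaFormatError("aligned rows differ in length (%d vs %d)",
                   nchar(targetText), nchar(queryText))
  t <- strsplit(toupper(targetText), "", fixed = TRUE)[[1L]]
  q <- strsplit(toupper(queryText), "", fixed = TRUE)[[1L]]
  legal <- c("A", "C", "G", "T", "N", "-")
  bad <- which(!(t %in% legal) | !(q %in% legal))
  if (length(bad))
    wgaFormatError("illegal character in alignment column %d ('%s'/'%s')",
                   bad[1L], t[bad[1L]], q[bad[1L]])
  dbl <- which(t == "-" & q == "-")
  if (length(dbl))
    wgaFormatError("double-gap alignment column %d", dbl[1L])
  op <- ifelse(t == "-", "I",
        ifelse(q == "-", "D",
        ifelse(t == q & t != "N", "=", "X")))
  Cigar(op, rep(1L, length(op)))
}

#' Summary statistics of a Cigar
#'
#' @param cigar a \linkS4class{Cigar}.
#' @return one-row data.frame: \code{matches}, \code{mismatches},
#'   \code{ambiguous} (M bases), \code{insEvents}, \code{insBases},
#'   \code{delEvents}, \code{delBases}, \code{alignedColumns} (sum of all run
#'   lengths). Events count runs; bases count summed lengths.
#' @export
#' @examples
#' cigarStats(Cigar("4=1X1=1D3="))
cigarStats <- function(cigar) {
  op <- cigar@ops; len <- cigar@lengths
  data.frame(
    matches = sum(len[op == "="]),
    mismatches = sum(len[op == "X"]),
    ambiguous = sum(len[op == "M"]),
    insEvents = sum(op == "I"),
    insBases = sum(len[op == "I"]),
    delEvents = sum(op == "D"),
    delBases = sum(len[op == "D"]),
    alignedColumns = sum(len)
  )
}
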