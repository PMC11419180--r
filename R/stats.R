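# Alignment statistics, filtering, coverage, pseudo-MAF projection and
# SNP/gap divergence.

#' Per-record alignment statistics
#'
#' A pure function of the cigar and coordinates. BLAST identity is matches
#' over aligned columns; gap-compressed identity is matches over matches +
#' mismatches + indel events (each gap run counted once).
#'
#' @param a an \linkS4class{AlignmentRecord}.
#' @return one-row data.frame (StatsRow): names, intervals, strand, counts,
#'   \code{blastIdentity}, \code{gapCompressedIdentity}.
#' @export
recordStats <- function(a) {
  st <- cigarStats(a@cigar)
  denomEvents <- st$matches + st$mismatches + st$ambiguous +
    st$insEvents + st$delEvents
  data.frame(
    queryName = a@queryName, queryStart = a@queryStart, queryEnd = a@queryEnd,
    strand = a@strand,
    targetName = a@targetName, targetStart = a@targetStart,
    targetEnd = a@targetEnd,
    alignedColumns = st$alignedColumns,
    matches = st$matches, mismatches = st$mismatches,
    ambiguous = st$ambiguous,
    insEvents = st$insEvents, insBases = st$insBases,
    delEvents = st$delEvents, delBases = st$delBases,
    blastIdentity = if (st$alignedColumns > 0) st$matches / st$alignedColumns
      else NA_real_,
    gapCompressedIdentity = if (denomEvents > 0) st$matches / denomEvents
      else NA_real_,
    stringsAsFactors = FALSE)
}

#' @rdname recordStats
#' @param records list of \linkS4class{AlignmentRecord}.
#' @return \code{alignmentStats}: one StatsRow per record.
#' @export
alignmentStats <- function(records) {
  do.call(rbind, lapply(records, recordStats))
}

#' Filter alignment records
#'
#' A record is kept iff its target span is at least \code{minBlockLength},
#' its query sequence size at least \code{minQuerySize}, and (when given)
#' \code{nameRegex} matches the query name. The tally counts rejections by
#' the first failing rule, in that order.
#'
#' @param records list of \linkS4class{AlignmentRecord}.
#' @param minBlockLength minimum target span in bp.
#' @param minQuerySize minimum query sequence length in bp.
#' @param nameRegex optional regular expression on the query name.
#' @return list with \code{kept} (records) and \code{tally} (named integer
#'   vector: \code{short_block}, \code{short_query}, \code{name_mismatch}).
#' @export
filterRecords <- function(records, minBlockLength = 0L, minQuerySize = 0L,
                          nameRegex = NULL) {
  if (!is.null(nameRegex)) {
    ok <- tryCatch({ grepl(nameRegex, "x"); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) wgaUsageError("invalid regular expression '%s'", nameRegex)
  }
  tally <- c(short_block = 0L, short_query = 0L, name_mismatch = 0L)
  kept <- list()
  for (a in records) {
    if (a@targetEnd - a@targetStart < minBlockLength) {
      tally["short_block"] <- tally["short_block"] + 1L
    } else if (a@querySize < minQuerySize) {
      tally["short_query"] <- tally["short_query"] + 1L
    } else if (!is.null(nameRegex) && !grepl(nameRegex, a@queryName)) {
      tally["name_mismatch"] <- tally["name_mismatch"] + 1L
    } else {
      kept[[length(kept) + 1L]] <- a
    }
  }
  list(kept = kept, tally = tally)
}

#' Reference coverage of a record set
#'
#' For each target sequence, the number of positions under at least one
#' alignment block (overlaps counted once, via interval union).
#'
#' @param records list of \linkS4class{AlignmentRecord}.
#' @return data.frame (CoverageRow): \code{targetName}, \code{targetLength},
#'   \code{covered}, \code{fraction}, \code{blocks}.
#' @export
alignmentCoverage <- function(records) {
  if (!length(records))
    return(data.frame(targetName = character(0), targetLength = integer(0),
                      covered = integer(0), fraction = numeric(0),
                      blocks = integer(0), stringsAsFactors = FALSE))
  tn <- vapply(records, targetName, character(1))
  ts <- vapply(records, targetSize, integer(1))
  out <- lapply(unique(tn), function(name) {
    idx <- which(tn == name)
    sizes <- unique(ts[idx])
    if (length(sizes) != 1L)
      wgaFormatError("conflicting target sizes for '%s'", name)
    ir <- IRanges::IRanges(
      start = vapply(records[idx], targetStart, integer(1)) + 1L,
      end = vapply(records[idx], targetEnd, integer(1)))
    covered <- sum(IRanges::width(IRanges::reduce(ir)))
    data.frame(targetName = name, targetLength = sizes,
               covered = covered, fraction = covered / sizes,
               blocks = length(idx), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Project query alignments onto reference coordinates (pseudo-MAF)
#'
#' Row 0 is the ungapped reference over the region. Each query genome gets
#' one reference-length row: the aligned query base at covered positions,
#' \code{x} where the alignment deletes the reference base, and \code{-}
#' where no block of that query covers the position. Insertion columns
#' (reference-gap) are dropped. When two blocks of one query overlap a
#' position, the longer block wins and the conflict is logged.
#'
#' @param refStore \code{\link{SequenceStore}} holding the reference.
#' @param records sequence-bearing \linkS4class{AlignmentRecord}s, all on the
#'   same target.
#' @param region a \linkS4class{Region} on the target.
#' @return list with \code{region}, \code{ref} (string) and \code{rows}
#'   (named character vector, one reference-length string per query).
#' @export
buildPseudoMaf <- function(refStore, records, region) {
  tnames <- unique(vapply(records, targetName, character(1)))
  if (length(tnames) > 1L)
    wgaUsageError("records target multiple references: %s",
                  paste(tnames, collapse = ", "))
  refSeq <- fetchSeq(refStore, region@name, region@start, region@end, "+")
  width <- region@end - region@start
  queries <- unique(vapply(records, queryName, character(1)))
  rows <- vapply(queries, function(qn) {
    row <- rep("-", width)
    recs <- Filter(function(a) a@queryName == qn, records)
    spans <- vapply(recs, function(a) a@targetEnd - a@targetStart, integer(1))
    conflict <- FALSE
    for (a in recs[order(spans)]) {   # longer blocks applied last -> win
      if (!hasTexts(a))
        wgaUsageError("pseudo-MAF requires sequence-bearing records")
      tch <- strsplit(a@targetText, "", fixed = TRUE)[[1L]]
      qch <- strsplit(a@queryText, "", fixed = TRUE)[[1L]]
      tcons <- tch != "-"
      tcoord <- rep(NA_integer_, length(tch))
      tcoord[tcons] <- a@targetStart + seq_len(sum(tcons)) - 1L
      sel <- which(tcons & tcoord >= region@start & tcoord < region@end)
      pos <- tcoord[sel] - region@start + 1L
      if (any(row[pos] != "-")) conflict <- TRUE
      row[pos] <- ifelse(qch[sel] == "-", "x", qch[sel])
    }
    if (conflict)
      message(sprintf("query %s: overlapping blocks in region; longer block wins",
                      qn))
    paste(row, collapse = "")
  }, character(1))
  list(region = region, ref = refSeq, rows = rows)
}

#' SNP and gap divergence from a pseudo-MAF block
#'
#' Rates are computed over covered positions (cells that are not \code{-}):
#' the SNP rate is the fraction of covered positions whose base differs from
#' the reference, the gap rate the fraction aligned as deleted (\code{x}).
#' A fully uncovered row reports both rates as 0 with \code{covered = 0}.
#'
#' @param pseudo result of \code{\link{buildPseudoMaf}}.
#' @return data.frame: \code{query}, \code{covered}, \code{snpRate},
#'   \code{gapRate}, \code{coveredFraction}.
#' @export
divergence <- function(pseudo) {
  refch <- strsplit(toupper(pseudo$ref), "", fixed = TRUE)[[1L]]
  width <- length(refch)
  out <- lapply(names(pseudo$rows), function(qn) {
    ch <- strsplit(pseudo$rows[[qn]], "", fixed = TRUE)[[1L]]
    cov <- ch != "-"
    n <- sum(cov)
    snp <- sum(cov & ch != "x" & toupper(ch) != refch)
    gap <- sum(ch == "x")
    data.frame(query = qn, covered = n,
               snpRate = if (n > 0) snp / n else 0,
               gapRate = if (n > 0) gap / n else 0,
               coveredFraction = n / width, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
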