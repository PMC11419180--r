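# Deterministic synthetic genome-pair generator: a uniform-random reference,
# a query derived from it by planted SNPs / insertions / deletions and an
# optional inverted segment, plus the truth MAF and truth variant list the
# construction implies. The substrate every other module is validated on.

BASES <- c("A", "C", "G", "T")

# Non-overlapping event placement by rejection sampling: footprints must be
# >= 2 bp apart and leave at least one match column at both alignment edges.
placeEvents <- function(refLength, spans) {
  occupied <- matrix(numeric(0), ncol = 2)
  pos <- integer(length(spans))
  for (i in seq_along(spans)) {
    span <- spans[i]
    hi <- refLength - 1L - span
    if (hi < 1L)
      wgaUsageError("event of span %d does not fit in reference of %d bp",
                    span, refLength)
    placed <- FALSE
    for (try in seq_len(10000L)) {
      p <- sample.int(hi, 1L)   # p in [1, hi]
      lo <- p; up <- p + span - 1L
      if (!nrow(occupied) ||
          all(lo > occupied[, 2] + 2 | up < occupied[, 1] - 2)) {
        occupied <- rbind(occupied, c(lo, up))
        pos[i] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed)
      wgaUsageError("could not place non-overlapping events (reference too short for the requested mutation load)")
  }
  pos
}

# Gapped texts for one alignment part [from, to) of the reference, applying
# the events whose footprints lie inside it. Positions are absolute 0-based.
buildAligned <- function(refChars, from, to, events) {
  tparts <- character(0); qparts <- character(0)
  pos <- from
  emitMatch <- function(upto) {
    if (upto > pos) {
      seg <- paste(refChars[(pos + 1L):upto], collapse = "")
      tparts <<- c(tparts, seg); qparts <<- c(qparts, seg)
    }
  }
  for (ev in events) {
    p <- ev$pos
    if (ev$type == "snp") {
      emitMatch(p)
      tparts <- c(tparts, refChars[p + 1L])
      qparts <- c(qparts, ev$alt)
      pos <- p + 1L
    } else if (ev$type == "ins") {
      emitMatch(p + 1L)
      tparts <- c(tparts, strrep("-", ev$len))
      qparts <- c(qparts, ev$seq)
      pos <- p + 1L
    } else if (ev$type == "del") {
      emitMatch(p + 1L)
      tparts <- c(tparts, paste(refChars[(p + 2L):(p + 1L + ev$len)],
                                collapse = ""))
      qparts <- c(qparts, strrep("-", ev$len))
      pos <- p + 1L + ev$len
    }
  }
  emitMatch(to)
  list(t = paste(tparts, collapse = ""), q = paste(qparts, collapse = ""))
}

#' Generate a synthetic reference/query genome pair with known mutations
#'
#' The reference is uniform-random ACGT under the seed; the query is built
#' by applying the planted events left to right. Event footprints are placed
#' by rejection sampling, pairwise at least 2 bp apart, never at the
#' alignment edges, and never overlapping the inverted segment. The truth
#' MAF encodes the exact alignment the construction implies (the inversion
#' as a separate minus-strand block between two plus-strand blocks); the
#' truth variant list follows the \code{\link{callVariants}} conventions
#' (left-anchored indels, SVTYPE/SVLEN for events of at least
#' \code{svThreshold} bases). Identical seeds give byte-identical outputs.
#'
#' @param refLength reference length in bp.
#' @param nSnps number of planted SNPs.
#' @param insertions,deletions integer vectors of event lengths in bp.
#' @param inversion optional length of one inverted segment.
#' @param seed RNG seed (the global RNG state is restored on exit).
#' @param svThreshold SV annotation threshold passed through to the truth
#'   list (default 50 bp).
#' @param refName,qryName sequence names.
#' @param outPrefix when given, writes \code{<p>.ref.fa}, \code{<p>.qry.fa},
#'   \code{<p>.truth.maf} and \code{<p>.truth.vcf}.
#' @return list: \code{refSeq}, \code{qrySeq} (strings), \code{refName},
#'   \code{qryName}, \code{records} (AlignmentRecords), \code{blocks}
#'   (truth MafBlocks), \code{variants} (truth calls, INV row included when
#'   planted), \code{store} (a \code{\link{SequenceStore}} of the pair).
#' @export
generatePair <- function(refLength = 1000L, nSnps = 0L,
                         insertions = integer(0), deletions = integer(0),
                         inversion = NULL, seed = 1L, svThreshold = 50L,
                         refName = "ref.chr1", qryName = "qry.chr1",
                         outPrefix = NULL) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  })
  set.seed(seed)
  refChars <- sample(BASES, refLength, replace = TRUE)

  insertions <- as.integer(insertions); deletions <- as.integer(deletions)
  # spans on the reference: SNP 1; INS anchor only; DEL anchor + deleted run;
  # INV its segment. The inversion is placed first (largest footprint).
  types <- c(if (!is.null(inversion)) "inv",
             rep("del", length(deletions)), rep("ins", length(insertions)),
             rep("snp", nSnps))
  lens <- c(if (!is.null(inversion)) as.integer(inversion),
            deletions, insertions, rep(1L, nSnps))
  spans <- ifelse(types == "snp", 1L,
           ifelse(types == "ins", 1L,
           ifelse(types == "del", lens + 1L, lens)))
  pos <- placeEvents(refLength, spans)

  events <- list()
  invEvent <- NULL
  for (i in seq_along(types)) {
    p <- pos[i]
    ev <- switch(types[i],
      snp = list(type = "snp", pos = p, len = 1L,
                 alt = sample(setdiff(BASES, refChars[p + 1L]), 1L)),
      ins = list(type = "ins", pos = p, len = lens[i],
                 seq = paste(sample(BASES, lens[i], replace = TRUE),
                             collapse = "")),
      del = list(type = "del", pos = p, len = lens[i]),
      inv = list(type = "inv", pos = p, len = lens[i]))
    if (ev$type == "inv") invEvent <- ev else
      events[[length(events) + 1L]] <- ev
  }
  events <- events[order(vapply(events, `[[`, integer(1), "pos"))]

  refSeq <- paste(refChars, collapse = "")
  records <- list()
  mkRecord <- function(texts, tFrom, tTo, qFrom) {
    qLen <- nchar(ungap(texts$q))
    list(texts = texts, tFrom = tFrom, tTo = tTo,
         qFrom = qFrom, qTo = qFrom + qLen)
  }
  if (is.null(invEvent)) {
    parts <- list(mkRecord(buildAligned(refChars, 0L, refLength, events),
                           0L, refLength, 0L))
  } else {
    s <- invEvent$pos; L <- invEvent$len
    evA <- Filter(function(e) e$pos < s, events)
    evC <- Filter(function(e) e$pos >= s + L, events)
    partA <- mkRecord(buildAligned(refChars, 0L, s, evA), 0L, s, 0L)
    invSegment <- paste(refChars[(s + 1L):(s + L)], collapse = "")
    partB <- list(texts = list(t = invSegment, q = invSegment),
                  tFrom = s, tTo = s + L,
                  qFrom = partA$qTo, qTo = partA$qTo + L)
    partC0 <- buildAligned(refChars, s + L, refLength, evC)
    partC <- mkRecord(partC0, s + L, refLength, partB$qTo)
    parts <- list(partA, partB, partC)
  }
  qrySize <- parts[[length(parts)]]$qTo
  strandOf <- function(i) if (!is.null(invEvent) && i == 2L) "-" else "+"
  qrySeqParts <- vapply(seq_along(parts), function(i) {
    q <- ungap(parts[[i]]$texts$q)
    if (strandOf(i) == "-") revcompStr(q) else q
  }, character(1))
  qrySeq <- paste(qrySeqParts, collapse = "")
  records <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    AlignmentRecord(qryName, qrySize, p$qFrom, p$qTo, strandOf(i),
                    refName, refLength, p$tFrom, p$tTo,
                    cigarFromTexts(p$texts$t, p$texts$q),
                    queryText = p$texts$q, targetText = p$texts$t)
  })
  blocks <- lapply(records, alignmentToMaf)

  qStartOf <- function(p) {
    for (part in parts)
      if (p >= part$tFrom && p < part$tTo) return(part$qFrom)
    parts[[1L]]$qFrom
  }
  vrows <- lapply(events, function(ev) {
    p <- ev$pos
    if (ev$type == "snp") {
      data.frame(contig = refName, pos = p + 1L, id = ".",
                 ref = refChars[p + 1L], alt = ev$alt, qual = ".",
                 filter = "PASS", svtype = NA_character_,
                 svlen = NA_integer_, qname = qryName,
                 qstart = qStartOf(p), stringsAsFactors = FALSE)
    } else if (ev$type == "ins") {
      big <- ev$len >= svThreshold
      data.frame(contig = refName, pos = p + 1L, id = ".",
                 ref = refChars[p + 1L],
                 alt = paste0(refChars[p + 1L], ev$seq), qual = ".",
                 filter = "PASS",
                 svtype = if (big) "INS" else NA_character_,
                 svlen = if (big) ev$len else NA_integer_,
                 qname = qryName, qstart = qStartOf(p),
                 stringsAsFactors = FALSE)
    } else {
      big <- ev$len >= svThreshold
      data.frame(contig = refName, pos = p + 1L, id = ".",
                 ref = paste(refChars[(p + 1L):(p + 1L + ev$len)],
                             collapse = ""),
                 alt = refChars[p + 1L], qual = ".", filter = "PASS",
                 svtype = if (big) "DEL" else NA_character_,
                 svlen = if (big) -ev$len else NA_integer_,
                 qname = qryName, qstart = qStartOf(p),
                 stringsAsFactors = FALSE)
    }
  })
  if (!is.null(invEvent)) {
    s <- invEvent$pos
    vrows[[length(vrows) + 1L]] <- data.frame(
      contig = refName, pos = s + 1L, id = ".", ref = refChars[s + 1L],
      alt = "<INV>", qual = ".", filter = "PASS", svtype = "INV",
      svlen = invEvent$len, qname = qryName, qstart = parts[[2L]]$qFrom,
      stringsAsFactors = FALSE)
  }
  variants <- if (length(vrows)) {
    v <- do.call(rbind, vrows)
    v <- v[order(v$pos), , drop = FALSE]
    rownames(v) <- NULL
    v
  } else emptyVariantFrame()

  store <- SequenceStore(stats::setNames(c(refSeq, qrySeq),
                                         c(refName, qryName)))
  if (!is.null(outPrefix)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(refSeq, refName)),
      paste0(outPrefix, ".ref.fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(qrySeq, qryName)),
      paste0(outPrefix, ".qry.fa"))
    writeMaf(blocks, paste0(outPrefix, ".truth.maf"))
    writeVcf(variants, stats::setNames(refLength, refName),
             paste0(outPrefix, ".truth.vcf"))
  }
  list(refName = refName, qryName = qryName, refSeq = refSeq,
       qrySeq = qrySeq, records = records, blocks = blocks,
       variants = variants, store = store, seed = seed)
}
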