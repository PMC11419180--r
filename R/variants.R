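# Alignment-signature variant calling: SNPs from X columns, left-anchored
# insertions/deletions from I/D runs, inversions from strand signatures.

#' Call variants from a sequence-bearing alignment record
#'
#' Walks the cigar over the gapped texts. Each mismatch column yields one
#' SNP (per column; no MNP merging). Each \code{I} run yields one insertion
#' and each \code{D} run one deletion, left-anchored in the VCF style: the
#' REF/ALT alleles start with the target base immediately left of the run.
#' A run at the alignment start has no left anchor and is skipped (tallied
#' in an attribute). Runs of at least \code{svThreshold} bases are annotated
#' with SVTYPE and signed SVLEN. Unresolved \code{M} runs are classified
#' column-by-column against the texts, so they behave like native
#' \code{=}/\code{X}.
#'
#' @param a an \linkS4class{AlignmentRecord} with texts present.
#' @param svThreshold minimum indel length for SVTYPE/SVLEN annotation
#'   (default 50 bp, the usual SV convention).
#' @param classes variant classes to emit, subset of
#'   \code{c("snp", "ins", "del")}.
#' @param minLen named integer vector of per-class minimum lengths, e.g.
#'   \code{c(ins = 10)}.
#' @return data.frame of calls sorted by position (columns \code{contig},
#'   \code{pos} (1-based), \code{id}, \code{ref}, \code{alt}, \code{qual},
#'   \code{filter}, \code{svtype}, \code{svlen}, \code{qname},
#'   \code{qstart}), with attribute \code{skipped} counting unanchored runs.
#' @export
#' @examples
#' a <- mafToAlignment(MafBlock(data.frame(
#'   src = c("ref.chr1", "qry.chr1"), start = 0L, size = c(10L, 9L),
#'   strand = "+", srcSize = c(10L, 9L),
#'   text = c("ACGTACGTAC", "ACGTTC-TAC"))))
#' callVariants(a)  # SNP at pos 5 (A>T) and deletion at pos 6 (CG>C)
callVariants <- function(a, svThreshold = 50L,
                         classes = c("snp", "ins", "del"),
                         minLen = c(snp = 1L, ins = 1L, del = 1L)) {
  if (!hasTexts(a))
    wgaUsageError("variant calling requires gapped texts (use a SequenceStore)")
  classes <- match.arg(classes, c("snp", "ins", "del"), several.ok = TRUE)
  minOf <- function(cls) if (cls %in% names(minLen)) minLen[[cls]] else 1L
  tch <- strsplit(a@targetText, "", fixed = TRUE)[[1L]]
  qch <- strsplit(a@queryText, "", fixed = TRUE)[[1L]]
  ops <- a@cigar@ops; lens <- a@cigar@lengths
  rows <- list(); nRows <- 0L
  push <- function(pos, ref, alt, svtype, svlen) {
    nRows <<- nRows + 1L
    rows[[nRows]] <<- list(contig = a@targetName, pos = pos, id = ".",
                           ref = ref, alt = alt, qual = ".", filter = "PASS",
                           svtype = svtype, svlen = svlen,
                           qname = a@queryName, qstart = a@queryStart)
  }
  col <- 0L          # columns consumed so far
  tpos <- a@targetStart  # next target coordinate (0-based)
  skipped <- 0L
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    idx <- col + seq_len(len)
    if (op %in% c("=", "X", "M")) {
      if ("snp" %in% classes) {
        mm <- if (op == "=") integer(0)
              else if (op == "X") seq_len(len)
              else which(toupper(tch[idx]) != toupper(qch[idx]) |
                         toupper(tch[idx]) == "N" | toupper(qch[idx]) == "N")
        for (j in mm)
          push(tpos + j, toupper(tch[idx[j]]), toupper(qch[idx[j]]),
               NA_character_, NA_integer_)
      }
      tpos <- tpos + len
    } else if (op == "I") {
      if (tpos == a@targetStart) {
        skipped <- skipped + 1L
      } else if ("ins" %in% classes && len >= minOf("ins")) {
        anchor <- toupper(tch[lastTargetCol(tch, col)])
        push(tpos, anchor,
             paste0(anchor, paste(toupper(qch[idx]), collapse = "")),
             if (len >= svThreshold) "INS" else NA_character_,
             if (len >= svThreshold) len else NA_integer_)
      }
    } else {  # D
      if (tpos == a@targetStart) {
        skipped <- skipped + 1L
      } else if ("del" %in% classes && len >= minOf("del")) {
        anchor <- toupper(tch[lastTargetCol(tch, col)])
        push(tpos, paste0(anchor, paste(toupper(tch[idx]), collapse = "")),
             anchor,
             if (len >= svThreshold) "DEL" else NA_character_,
             if (len >= svThreshold) -len else NA_integer_)
      }
      tpos <- tpos + len
    }
    col <- col + len
  }
  out <- if (nRows) do.call(rbind, lapply(rows[seq_len(nRows)],
                                          as.data.frame)) else
    emptyVariantFrame()
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# rightmost target-consuming column at or before column `col`
lastTargetCol <- function(tch, col) {
  j <- col
  while (j >= 1L && tch[j] == "-") j <- j - 1L
  j
}

#' Call inversions from strand signatures
#'
#' Within each (query, target) group, a minus-strand record whose target
#' interval is flanked by plus-strand records of the same query (one ending
#' at or before its start, one starting at or after its end) is reported as
#' one INV spanning its target interval. REF is the target base at the
#' position (taken from the record's text); ALT is the symbolic
#' \code{<INV>}. This is a heuristic: a lone minus-strand record without
#' flanks produces no call.
#'
#' @param records list of \linkS4class{AlignmentRecord}.
#' @return data.frame of INV calls in the \code{\link{callVariants}} layout.
#' @export
callInversions <- function(records) {
  if (!length(records)) return(emptyVariantFrame())
  key <- vapply(records, function(a) paste(a@queryName, a@targetName,
                                           sep = "\r"), character(1))
  out <- list()
  for (k in unique(key)) {
    grp <- records[key == k]
    strands <- vapply(grp, alnStrand, character(1))
    ts <- vapply(grp, targetStart, integer(1))
    te <- vapply(grp, targetEnd, integer(1))
    for (i in which(strands == "-")) {
      hasLeft <- any(strands == "+" & te <= ts[i])
      hasRight <- any(strands == "+" & ts >= te[i])
      if (!(hasLeft && hasRight)) next
      a <- grp[[i]]
      refBase <- if (hasTexts(a)) {
        tch <- strsplit(a@targetText, "", fixed = TRUE)[[1L]]
        toupper(tch[tch != "-"][1L])
      } else "N"
      out[[length(out) + 1L]] <- data.frame(
        contig = a@targetName, pos = a@targetStart + 1L, id = ".",
        ref = refBase, alt = "<INV>", qual = ".", filter = "PASS",
        svtype = "INV", svlen = a@targetEnd - a@targetStart,
        qname = a@queryName, qstart = a@queryStart,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(emptyVariantFrame())
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Apply SNP/INS/DEL calls to a target subsequence
#'
#' The self-validation oracle of the caller: editing the target subsequence
#' of a record with its own calls must reproduce the (ungapped, aligned-
#' orientation) query subsequence exactly. Inversion records are ignored.
#'
#' @param targetSeq ungapped target subsequence covering
#'   \code{[targetStart, targetEnd)}.
#' @param variants data.frame of calls (1-based \code{pos} on the target).
#' @param targetStart 0-based target coordinate of \code{targetSeq[1]}.
#' @return the edited sequence.
#' @export
applyVariants <- function(targetSeq, variants, targetStart = 0L) {
  v <- variants[is.na(variants$svtype) | variants$svtype != "INV", ,
                drop = FALSE]
  # right-to-left so earlier edits don't shift later positions; at a shared
  # anchor position the indel must be applied before the SNP, because the
  # indel's REF anchor is the pre-SNP target base
  isSnp <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
  v <- v[order(-v$pos, isSnp), , drop = FALSE]
  seq <- toupper(targetSeq)
  for (i in seq_len(nrow(v))) {
    rel <- v$pos[i] - targetStart     # 1-based position within seq
    ref <- v$ref[i]; alt <- v$alt[i]
    if (substr(seq, rel, rel + nchar(ref) - 1L) != ref)
      wgaFormatError("REF mismatch at %s:%d", v$contig[i], v$pos[i])
    seq <- paste0(substr(seq, 1L, rel - 1L), alt,
                  substr(seq, rel + nchar(ref), nchar(seq)))
  }
  seq
}
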