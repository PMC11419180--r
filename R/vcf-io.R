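# VCF v4.2 writer for alignment-derived variant calls.
#
# Calls are carried as a plain data.frame (one row per record) rather than a
# per-record S4 object: columns contig, pos (1-based), id, ref, alt, qual,
# filter, svtype (NA / "INS" / "DEL" / "INV"), svlen (signed, NA for SNPs),
# qname, qstart (provenance).

emptyVariantFrame <- function() {
  data.frame(contig = character(0), pos = integer(0), id = character(0),
             ref = character(0), alt = character(0), qual = character(0),
             filter = character(0), svtype = character(0),
             svlen = integer(0), qname = character(0), qstart = integer(0),
             stringsAsFactors = FALSE)
}

vcfInfoField <- function(v, provenance = TRUE) {
  info <- ifelse(is.na(v$svtype), "",
                 sprintf("SVTYPE=%s;SVLEN=%d", v$svtype, v$svlen))
  if (provenance && "qname" %in% names(v)) {
    prov <- ifelse(is.na(v$qname), "",
                   sprintf("QNAME=%s;QSTART=%d", v$qname, v$qstart))
    info <- ifelse(info == "", prov,
                   ifelse(prov == "", info, paste(info, prov, sep = ";")))
  }
  ifelse(info == "", ".", info)
}

#' Write variant calls as VCF v4.2
#'
#' Emits a header (fileformat, contig lines, INFO definitions for
#' SVTYPE/SVLEN and the QNAME/QSTART provenance fields) followed by
#' 8-column body lines. Records must already be sorted by (contig, pos).
#'
#' @param variants data.frame of calls as returned by
#'   \code{\link{callVariants}}.
#' @param contigs named integer vector: contig name -> length.
#' @param path output path (\code{"-"} for standard output).
#' @param provenance include QNAME/QSTART in INFO.
#' @export
writeVcf <- function(variants, contigs, path, provenance = TRUE) {
  if (nrow(variants)) {
    o <- order(variants$contig, variants$pos)
    if (!identical(o, seq_len(nrow(variants))))
      wgaUsageError("variant records must be sorted by (contig, position)")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Signed length of structural variant">',
    '##INFO=<ID=QNAME,Number=1,Type=String,Description="Query sequence name">',
    '##INFO=<ID=QSTART,Number=1,Type=Integer,Description="Query start of the source alignment (0-based)">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants)) {
    sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
            variants$contig, variants$pos, variants$id, variants$ref,
            variants$alt, variants$qual, variants$filter,
            vcfInfoField(variants, provenance))
  } else character(0)
  writeAllLines(c(header, body), path)
}

#' Read back a VCF body into the call data.frame (header-light parser used
#' for round-trip checks and the truth files of the synthetic generator).
#' @param path VCF path.
#' @return data.frame in the \code{\link{callVariants}} layout.
#' @export
readVcfCalls <- function(path) {
  lines <- readAllLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) return(emptyVariantFrame())
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  getInfo <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
           character(1))
  }
  data.frame(contig = f[, 1L], pos = as.integer(f[, 2L]), id = f[, 3L],
             ref = f[, 4L], alt = f[, 5L], qual = f[, 6L], filter = f[, 7L],
             svtype = getInfo(f[, 8L], "SVTYPE"),
             svlen = as.integer(getInfo(f[, 8L], "SVLEN")),
             qname = getInfo(f[, 8L], "QNAME"),
             qstart = as.integer(getInfo(f[, 8L], "QSTART")),
             stringsAsFactors = FALSE)
}
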