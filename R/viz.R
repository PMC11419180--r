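# Static visualization: dot-plot segments (overview and base resolution),
# deterministic SVG rendering, and a terminal-style block renderer.

#' Dot-plot segments from alignment records
#'
#' Overview mode emits one \code{record} segment per alignment from
#' \code{(tStart, qStart)} to \code{(tEnd, qEnd)} (reflected on the query
#' axis for minus-strand records, so they render anti-diagonal). Base mode
#' walks the cigar: every \code{=}/\code{X}/\code{M} run becomes one
#' diagonal segment; \code{I}/\code{D} runs advance one axis only and emit
#' nothing.
#'
#' @param records list of \linkS4class{AlignmentRecord}.
#' @param mode \code{"overview"} or \code{"base"}.
#' @return data.frame (DotSegment): \code{targetName}, \code{queryName},
#'   \code{t0}, \code{t1}, \code{q0}, \code{q1}, \code{kind}, \code{strand}.
#' @export
dotplotSegments <- function(records, mode = c("overview", "base")) {
  mode <- match.arg(mode)
  seg <- function(a, t0, t1, q0, q1, kind) {
    data.frame(targetName = a@targetName, queryName = a@queryName,
               t0 = t0, t1 = t1, q0 = q0, q1 = q1, kind = kind,
               strand = a@strand, stringsAsFactors = FALSE)
  }
  out <- lapply(records, function(a) {
    if (mode == "overview") {
      if (a@strand == "+")
        return(seg(a, a@targetStart, a@targetEnd, a@queryStart, a@queryEnd,
                   "record"))
      return(seg(a, a@targetStart, a@targetEnd, a@queryEnd, a@queryStart,
                 "record"))
    }
    ops <- a@cigar@ops; lens <- a@cigar@lengths
    toff <- a@targetStart
    qoff <- if (a@strand == "+") a@queryStart else a@queryEnd
    dirq <- if (a@strand == "+") 1L else -1L
    segs <- list()
    for (i in seq_along(ops)) {
      len <- lens[i]
      if (ops[i] %in% c("=", "X", "M")) {
        segs[[length(segs) + 1L]] <-
          seg(a, toff, toff + len, qoff, qoff + dirq * len,
              if (ops[i] == "X") "mismatch" else "match")
        toff <- toff + len
        qoff <- qoff + dirq * len
      } else if (ops[i] == "D") {
        toff <- toff + len
      } else {
        qoff <- qoff + dirq * len
      }
    }
    do.call(rbind, segs)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(targetName = character(0), queryName = character(0),
                      t0 = integer(0), t1 = integer(0), q0 = integer(0),
                      q1 = integer(0), kind = character(0),
                      strand = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

SVG_STYLE <- c(match = "stroke:#1f6feb;stroke-width:1.5",
               mismatch = "stroke:#d1242f;stroke-width:1.5",
               record = "stroke:#57606a;stroke-width:1")

#' Render dot-plot segments as an SVG document
#'
#' Axes are scaled to the maximum target/query coordinates; every segment
#' becomes one \code{<line>} element, styled by kind, minus-strand segments
#' anti-diagonal. Output is deterministic for a fixed input.
#'
#' @param segments data.frame from \code{\link{dotplotSegments}}.
#' @param widthPx,heightPx canvas size in pixels.
#' @return single string: the SVG document.
#' @export
renderSvg <- function(segments, widthPx = 600, heightPx = 600) {
  pad <- 40
  tMax <- if (nrow(segments)) max(segments$t0, segments$t1) else 1
  qMax <- if (nrow(segments)) max(segments$q0, segments$q1) else 1
  tMax <- max(tMax, 1); qMax <- max(qMax, 1)
  sx <- function(t) pad + (widthPx - 2 * pad) * t / tMax
  sy <- function(q) heightPx - pad - (heightPx - 2 * pad) * q / qMax
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            as.integer(widthPx), as.integer(heightPx)),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="white"/>',
            as.integer(widthPx), as.integer(heightPx)),
    # axes
    sprintf('<path d="M %s %s L %s %s L %s %s" fill="none" stroke="black"/>',
            fmt(sx(0)), fmt(sy(qMax)), fmt(sx(0)), fmt(sy(0)),
            fmt(sx(tMax)), fmt(sy(0))))
  if (nrow(segments)) {
    lines <- c(lines, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" style="%s"/>',
      fmt(sx(segments$t0)), fmt(sy(segments$q0)),
      fmt(sx(segments$t1)), fmt(sy(segments$q1)),
      SVG_STYLE[segments$kind]))
  }
  paste(c(lines, "</svg>"), collapse = "\n")
}

#' @rdname renderSvg
#' @param path output TSV path.
#' @export
writeSegmentsTsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Render a pairwise MAF block as wrapped text
#'
#' The static core of a terminal alignment viewer: paired, coordinate-
#' labelled rows wrapped to the requested width. With
#' \code{highlight = "variants"} a third marker line flags mismatch columns
#' with \code{*} and gap columns with \code{-}.
#'
#' @param b a pairwise \linkS4class{MafBlock}.
#' @param width maximum output line width in columns (>= 20).
#' @param highlight \code{"variants"} or \code{"none"}.
#' @return character vector of lines.
#' @export
renderBlockText <- function(b, width = 80L, highlight = c("variants", "none")) {
  highlight <- match.arg(highlight)
  if (width < 20L) wgaUsageError("width must be >= 20 columns")
  r <- b@rows
  if (nrow(r) != 2L)
    wgaFormatError("text rendering requires a pairwise block")
  tch <- strsplit(r$text[1L], "", fixed = TRUE)[[1L]]
  qch <- strsplit(r$text[2L], "", fixed = TRUE)[[1L]]
  marker <- ifelse(tch == "-" | qch == "-", "-",
                   ifelse(toupper(tch) == toupper(qch) & toupper(tch) != "N",
                          " ", "*"))
  labWidth <- max(nchar(r$src)) +
    nchar(as.character(max(r$start + r$size))) + 2L
  chunk <- max(width - labWidth, 1L)
  ncols <- length(tch)
  starts <- seq(1L, ncols, by = chunk)
  # running strand-relative coordinate of the first base in each chunk
  tconsumed <- cumsum(tch != "-")
  qconsumed <- cumsum(qch != "-")
  out <- character(0)
  for (s in starts) {
    e <- min(s + chunk - 1L, ncols)
    tpos <- r$start[1L] + (if (s == 1L) 0L else tconsumed[s - 1L])
    qpos <- r$start[2L] + (if (s == 1L) 0L else qconsumed[s - 1L])
    lab1 <- formatC(sprintf("%s %d", r$src[1L], tpos), width = labWidth,
                    flag = "-")
    lab2 <- formatC(sprintf("%s %d", r$src[2L], qpos), width = labWidth,
                    flag = "-")
    out <- c(out,
             paste0(lab1, paste(tch[s:e], collapse = "")),
             paste0(lab2, paste(qch[s:e], collapse = "")))
    if (highlight == "variants")
      out <- c(out, paste0(strrep(" ", labWidth),
                           paste(marker[s:e], collapse = "")))
  }
  out
}
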