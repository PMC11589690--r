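#' Read RepeatMasker .out annotations
#'
#' Standard RepeatMasker layout: three header lines then whitespace-delimited
#' columns (SW score, % divergence, % deletion, % insertion, query, query
#' begin, query end, query left, strand, repeat name, repeat class/family,
#' ...).  Query begin/end are 1-based inclusive and map directly onto the
#' returned \code{GRanges}; the \code{C} (complement) strand code is
#' normalized to \code{-}.
#'
#' @param path path to a RepeatMasker .out file.
#' @return \code{GRanges} with metadata columns \code{family}, \code{class}
#'   and \code{divergence} (percent mismatch to consensus).
#' @export
readRepeatMaskerOut <- function(path) {
    lines <- readLines(path)
    # header = leading lines up to the first blank separator (3 in standard output)
    body <- lines
    if (length(lines) >= 3L &&
        (grepl("\\bSW\\b|score", lines[1L]) || grepl("score", lines[2L])))
        body <- lines[-(1:3)]
    body <- body[nzchar(trimws(body))]
    if (!length(body)) {
        gr <- GRanges()
        mcols(gr)$family <- character()
        mcols(gr)$class <- character()
        mcols(gr)$divergence <- numeric()
        return(gr)
    }
    parts <- strsplit(trimws(body), "[[:space:]]+")
    short <- which(lengths(parts) < 14L)
    if (length(short))
        stop("RepeatMasker line with fewer than 14 columns (body line ",
             short[1L], ")")
    fld <- function(i) vapply(parts, `[`, "", i)
    div <- as.numeric(fld(2L))
    if (any(is.na(div) | div < 0 | div > 100))
        stop("divergence outside [0,100]")
    qbeg <- as.integer(fld(6L))
    qend <- as.integer(fld(7L))
    strand <- ifelse(fld(9L) == "C", "-", fld(9L))
    gr <- GRanges(fld(5L), IRanges(qbeg, qend), strand = strand)
    mcols(gr)$family <- fld(10L)
    mcols(gr)$class <- fld(11L)
    mcols(gr)$divergence <- div
    gr
}

#' Write repeat hits in RepeatMasker .out layout
#'
#' Emits the standard 15-column layout with the three header lines, so the
#' result round-trips through \code{\link{readRepeatMaskerOut}}.
#'
#' @param hits \code{GRanges} with \code{family}, \code{class} and
#'   \code{divergence} metadata columns.
#' @param path output path.
#' @export
writeRepeatMaskerOut <- function(hits, path) {
    hdr <- c(paste("  SW  perc perc perc  query     position in query",
                   "    matching  repeat         position in repeat"),
             paste("score  div. del. ins.  sequence  begin  end   (left)",
                   "   repeat    class/family   begin  end (left)  ID"),
             "")
    st <- as.character(strand(hits))
    st[st %in% c("*", "+")] <- "+"
    st[st == "-"] <- "C"
    rows <- sprintf(" 1000 %5.1f  0.0  0.0  %s %d %d (0) %s %s %s 1 %d (0) %d",
                    mcols(hits)$divergence, as.character(seqnames(hits)),
                    start(hits), end(hits), st, mcols(hits)$family,
                    mcols(hits)$class, width(hits), seq_along(hits))
    writeLines(c(hdr, rows), path)
    invisible(path)
}
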