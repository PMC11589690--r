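#' Read a BED3/BED4+ file
#'
#' BED is 0-based half-open on disk; the returned \code{GRanges} follows the
#' usual 1-based closed convention, so \code{start(gr) == bedStart + 1} and
#' \code{end(gr) == bedEnd}.  Column 4, when present, becomes the range names
#' and a \code{name} metadata column.
#'
#' @param path path to a BED file.
#' @return \code{GRanges}.
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    idx <- which(keep)
    if (!length(idx))
        return(GRanges())
    parts <- strsplit(lines[idx], "\t", fixed = TRUE)
    ncols <- lengths(parts)
    if (any(ncols < 3L))
        stop("malformed BED line ", idx[which(ncols < 3L)[1L]],
             ": fewer than 3 tab-separated columns")
    chrom <- vapply(parts, `[`, "", 1L)
    s <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    e <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
    if (anyNA(s) || anyNA(e))
        stop("malformed BED line ", idx[which(is.na(s) | is.na(e))[1L]],
             ": non-numeric coordinates")
    bad <- which(s >= e | s < 0)
    if (length(bad))
        stop("invalid interval at line ", idx[bad[1L]],
             ": require 0 <= start < end")
    if (!nzchar(chrom[1L]) || any(!nzchar(chrom)))
        stop("empty chromosome name at line ", idx[which(!nzchar(chrom))[1L]])
    gr <- GRanges(chrom, IRanges(s + 1, e))
    if (all(ncols >= 4L)) {
        nm <- vapply(parts, `[`, "", 4L)
        names(gr) <- nm
        mcols(gr)$name <- nm
    }
    gr
}

#' Write intervals as BED
#'
#' @param gr \code{GRanges}; a \code{name} metadata column (or names) becomes
#'   BED column 4.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = format(start(gr) - 1, scientific = FALSE, trim = TRUE),
                     end = format(end(gr), scientific = FALSE, trim = TRUE),
                     stringsAsFactors = FALSE)
    nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else names(gr)
    if (!is.null(nm)) df$name <- nm
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a sample-sex table
#'
#' Two tab-separated columns: sample id and sex (\code{M} or \code{F}).
#'
#' @param path path to the TSV.
#' @return named character vector of "M"/"F".
#' @export
readSexLabels <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("sample", "sex"))
    if (!all(df$sex %in% c("M", "F")))
        stop("sex column must be 'M' or 'F'")
    stats::setNames(df$sex, df$sample)
}

#' Write a sample-sex table
#' @param sex named character vector of "M"/"F".
#' @param path output path.
#' @export
writeSexLabels <- function(sex, path) {
    utils::write.table(data.frame(names(sex), unname(sex)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}
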