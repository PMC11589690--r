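#' Read pairwise whole-genome alignment blocks
#'
#' Both supported dialects map onto the same \linkS4class{AlignmentBlocks}
#' container:
#' \describe{
#'   \item{\code{paf}}{minimap2-style PAF (12+ tab-separated columns).  The
#'     PAF target is the reference side; PAF coordinates are 0-based
#'     half-open and are converted to the 1-based closed \code{GRanges}
#'     convention.  Identity is \code{100 * matches / alignment length}.}
#'   \item{\code{coords}}{MUMmer \code{show-coords -T} tab layout:
#'     S1 E1 S2 E2 LEN1 LEN2 \%IDY REF QUERY.  Coordinates are 1-based
#'     inclusive; a reversed query interval (S2 > E2) encodes the minus
#'     strand and is normalized to ascending coordinates.}
#' }
#'
#' @param path input path.
#' @param dialect \code{"paf"} or \code{"coords"}.
#' @return an \linkS4class{AlignmentBlocks}.
#' @export
readAlignmentBlocks <- function(path, dialect = c("paf", "coords")) {
    dialect <- match.arg(dialect)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (dialect == "coords") {
        # drop any show-coords preamble (header ends with a line of '=' or the
        # [S1] tag line); keep rows whose first field is numeric
        first <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
        lines <- lines[!is.na(suppressWarnings(as.numeric(first)))]
    }
    if (!length(lines))
        return(AlignmentBlocks(GRanges(), GRanges(), character(), numeric()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (dialect == "paf") {
        if (any(lengths(parts) < 12L))
            stop("PAF line with fewer than 12 columns")
        fld <- function(i) vapply(parts, `[`, "", i)
        num <- function(i) as.numeric(fld(i))
        strand <- fld(5L)
        qry <- GRanges(fld(1L), IRanges(num(3L) + 1, num(4L)))
        ref <- GRanges(fld(6L), IRanges(num(8L) + 1, num(9L)))
        identity <- 100 * num(10L) / num(11L)
    } else {
        if (any(lengths(parts) < 9L))
            stop("show-coords TSV line with fewer than 9 columns")
        fld <- function(i) vapply(parts, `[`, "", i)
        num <- function(i) as.numeric(fld(i))
        s1 <- num(1L); e1 <- num(2L); s2 <- num(3L); e2 <- num(4L)
        strand <- ifelse(s2 > e2, "-", "+")
        ref <- GRanges(fld(8L), IRanges(pmin(s1, e1), pmax(s1, e1)))
        qry <- GRanges(fld(9L), IRanges(pmin(s2, e2), pmax(s2, e2)))
        identity <- num(7L)
    }
    if (any(is.na(identity) | identity < 0 | identity > 100))
        stop("identity outside [0,100]")
    AlignmentBlocks(ref, qry, strand, identity)
}

#' Write alignment blocks as PAF
#'
#' @param blocks an \linkS4class{AlignmentBlocks}.
#' @param path output path.
#' @export
writePaf <- function(blocks, path) {
    ref <- refRanges(blocks); qry <- queryRanges(blocks)
    alen <- pmax(width(ref), width(qry))
    nmatch <- round(blockIdentity(blocks) / 100 * alen)
    qlen <- if (!anyNA(GenomeInfoDb::seqlengths(qry)) &&
                length(GenomeInfoDb::seqlengths(qry)))
        GenomeInfoDb::seqlengths(qry)[as.character(seqnames(qry))]
    else end(qry)
    tlen <- if (!anyNA(GenomeInfoDb::seqlengths(ref)) &&
                length(GenomeInfoDb::seqlengths(ref)))
        GenomeInfoDb::seqlengths(ref)[as.character(seqnames(ref))]
    else end(ref)
    rows <- paste(as.character(seqnames(qry)), qlen, start(qry) - 1, end(qry),
                  blockStrand(blocks),
                  as.character(seqnames(ref)), tlen, start(ref) - 1, end(ref),
                  nmatch, alen, 60L, sep = "\t")
    writeLines(rows, path)
    invisible(path)
}

#' Write alignment blocks in show-coords -T tab layout
#'
#' @param blocks an \linkS4class{AlignmentBlocks}.
#' @param path output path.
#' @export
writeCoordsTsv <- function(blocks, path) {
    ref <- refRanges(blocks); qry <- queryRanges(blocks)
    minus <- blockStrand(blocks) == "-"
    s2 <- ifelse(minus, end(qry), start(qry))
    e2 <- ifelse(minus, start(qry), end(qry))
    rows <- paste(start(ref), end(ref), s2, e2, width(ref), width(qry),
                  format(blockIdentity(blocks), trim = TRUE),
                  as.character(seqnames(ref)), as.character(seqnames(qry)),
                  sep = "\t")
    writeLines(rows, path)
    invisible(path)
}
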