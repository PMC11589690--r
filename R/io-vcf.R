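#' Read a VCF into a VariantCalls object
#'
#' Parses the fields the pipeline consumes: CHROM/POS/REF/ALT/QUAL and the
#' per-sample GT (with phase encoded by the \code{|} separator), DP and GQ.
#' VCF POS is 1-based; so is the returned \code{GRanges}, whose width equals
#' the REF allele length (1 for SNVs).
#'
#' @param path path to an uncompressed VCF 4.x file.
#' @param sex optional named sex vector to attach to the samples.
#' @return a \linkS4class{VariantCalls}.
#' @export
readVariantVcf <- function(path, sex = NULL) {
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines)
    if (!length(hdr)) stop("no #CHROM header line in ", path)
    cols <- strsplit(lines[hdr[1L]], "\t", fixed = TRUE)[[1L]]
    samples <- if (length(cols) > 9L) cols[-(1:9)] else character()
    body <- lines[-seq_len(hdr[1L])]
    body <- body[nzchar(body)]
    n <- length(body)
    if (!n) {
        return(VariantCalls(GRanges(), character(), list(), numeric(),
                            matrix(NA_integer_, 0, length(samples),
                                   dimnames = list(NULL, samples)),
                            sex = sex))
    }
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != length(cols)))
        stop("VCF body row has wrong number of columns (sample mismatch?)")
    fld <- function(i) vapply(parts, `[`, "", i)
    chrom <- fld(1L)
    pos <- as.integer(fld(2L))
    ref <- fld(4L)
    alt <- strsplit(fld(5L), ",", fixed = TRUE)
    qualStr <- fld(6L)
    qual <- suppressWarnings(as.numeric(qualStr))
    fmt <- strsplit(fld(9L), ":", fixed = TRUE)
    a1 <- matrix(NA_integer_, n, length(samples),
                 dimnames = list(NULL, samples))
    a2 <- a1
    ph <- matrix(FALSE, n, length(samples), dimnames = list(NULL, samples))
    dp <- a1
    gq <- matrix(NA_real_, n, length(samples), dimnames = list(NULL, samples))
    if (length(samples)) {
        gtIdx <- vapply(fmt, function(f) match("GT", f), 0L)
        if (anyNA(gtIdx)) stop("FORMAT without GT at row ",
                               which(is.na(gtIdx))[1L])
        dpIdx <- vapply(fmt, function(f) match("DP", f), 0L)
        gqIdx <- vapply(fmt, function(f) match("GQ", f), 0L)
        for (j in seq_along(samples)) {
            sm <- strsplit(fld(9L + j), ":", fixed = TRUE)
            gt <- mapply(function(v, i) v[i], sm, gtIdx)
            ph[, j] <- grepl("|", gt, fixed = TRUE)
            al <- strsplit(gt, "[/|]")
            one <- vapply(al, `[`, "", 1L)
            two <- vapply(al, function(v) if (length(v) > 1L) v[2L] else NA_character_, "")
            a1[, j] <- suppressWarnings(as.integer(one))
            a2[, j] <- suppressWarnings(as.integer(two))
            getf <- function(idx) mapply(function(v, i)
                if (is.na(i) || length(v) < i) NA_character_ else v[i], sm, idx)
            dp[, j] <- suppressWarnings(as.integer(getf(dpIdx)))
            gq[, j] <- suppressWarnings(as.numeric(getf(gqIdx)))
        }
    }
    gr <- GRanges(chrom, IRanges(pos, width = nchar(ref)))
    VariantCalls(gr, REF = ref, ALT = alt, QUAL = qual,
                 alleleA = a1, alleleB = a2, phased = ph, DP = dp, GQ = gq,
                 sex = sex)
}

#' Write a VariantCalls object as VCF 4.2
#'
#' Haploid panels (all \code{alleleB} missing while \code{alleleA} is called)
#' are written with single-allele GT fields; phased diploid genotypes use the
#' \code{|} separator.
#'
#' @param x a \linkS4class{VariantCalls}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVariantVcf <- function(x, path) {
    gr <- rowRanges(x)
    o <- order(as.character(seqnames(gr)), start(gr), method = "radix")
    x <- x[o, ]
    gr <- rowRanges(x)
    samples <- colnames(x)
    hdr <- c("##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
    sl <- GenomeInfoDb::seqlengths(gr)
    if (length(sl) && !anyNA(sl))
        hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(sl), sl))
    hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO", "FORMAT", samples),
                        collapse = "\t"))
    a1 <- assay(x, "alleleA"); a2 <- assay(x, "alleleB")
    ph <- assay(x, "phased"); dp <- assay(x, "DP"); gq <- assay(x, "GQ")
    n <- nrow(x)
    fmtNum <- function(v) ifelse(is.na(v), ".", format(v, trim = TRUE))
    gtcols <- vapply(seq_along(samples), function(j) {
        g1 <- ifelse(is.na(a1[, j]), ".", a1[, j])
        hap <- is.na(a2[, j]) & !is.na(a1[, j])
        sep <- ifelse(ph[, j] & !is.na(ph[, j]), "|", "/")
        g <- ifelse(hap, g1,
                    paste0(g1, sep, ifelse(is.na(a2[, j]), ".", a2[, j])))
        paste(g, fmtNum(dp[, j]), fmtNum(gq[, j]), sep = ":")
    }, character(n))
    if (n == 1L) gtcols <- matrix(gtcols, nrow = 1L)
    alt <- vapply(as.list(altAlleles(x)), function(a)
        if (!length(a)) "." else paste(a, collapse = ","), "")
    rows <- paste(as.character(seqnames(gr)), start(gr), ".",
                  refAllele(x), alt, fmtNum(siteQual(x)), ".", ".",
                  "GT:DP:GQ", sep = "\t")
    if (length(samples))
        rows <- paste(rows, apply(gtcols, 1L, paste, collapse = "\t"),
                      sep = "\t")
    writeLines(c(hdr, rows), path)
    invisible(path)
}
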