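#' Filter whole-genome alignment blocks
#'
#' Keeps blocks with percent identity at least \code{minIdentity} and
#' reference length at least \code{minLength} bp.  Idempotent.
#'
#' @param blocks an \linkS4class{AlignmentBlocks}.
#' @param minIdentity minimum percent identity (default 95).
#' @param minLength minimum reference-side length in bp (default 2000).
#' @return the retained \linkS4class{AlignmentBlocks}.
#' @export
filterBlocks <- function(blocks, minIdentity = 95, minLength = 2000) {
    keep <- blockIdentity(blocks) >= minIdentity &
        width(refRanges(blocks)) >= minLength
    blocks[keep]
}

#' Count SNPs and indel events in aligned block sequence pairs
#'
#' A SNP is an aligned column with two different non-gap bases; an indel is
#' a maximal run of gap columns in either sequence, counted as one event.
#' Per-Mb medians are taken over the 1 Mb reference bins intersecting the
#' blocks.
#'
#' @param alignments list of length-2 character vectors (or lists) with the
#'   gapped reference and query sequence per block.
#' @param refRanges optional \code{GRanges} of the blocks' reference
#'   intervals, enabling the per-Mb summaries.
#' @param binSize reference bin width (default 1e6).
#' @return list: \code{perBlock} data.frame (snps, indels),
#'   \code{totalSnps}, \code{totalIndels}, and when \code{refRanges} is
#'   given \code{perMb} data.frame with \code{medianSnpsPerMb} and
#'   \code{medianIndelsPerMb} attributes.
#' @export
countBlockVariants <- function(alignments, refRanges = NULL, binSize = 1e6) {
    n <- length(alignments)
    snps <- indels <- integer(n)
    snpPos <- vector("list", n)   # reference offsets (1-based within block)
    indelPos <- vector("list", n)
    for (i in seq_len(n)) {
        a <- strsplit(toupper(as.character(alignments[[i]][[1L]])), "")[[1L]]
        b <- strsplit(toupper(as.character(alignments[[i]][[2L]])), "")[[1L]]
        if (length(a) != length(b))
            stop("block ", i, ": aligned lengths differ")
        gap <- a == "-" | b == "-"
        refPos <- cumsum(a != "-")
        isSnp <- !gap & a != b
        snps[i] <- sum(isSnp)
        snpPos[[i]] <- refPos[isSnp]
        if (any(gap)) {
            r <- rle(gap)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            runs <- which(r$values)
            indels[i] <- length(runs)
            indelPos[[i]] <- pmax(1L, refPos[starts[runs]])
        }
    }
    out <- list(perBlock = data.frame(snps = snps, indels = indels),
                totalSnps = sum(snps), totalIndels = sum(indels))
    if (!is.null(refRanges)) {
        stopifnot(length(refRanges) == n)
        toGenome <- function(posList) {
            gp <- unlist(mapply(function(p, s) s + p - 1L, posList,
                                start(refRanges), SIMPLIFY = FALSE))
            ch <- rep(as.character(seqnames(refRanges)), lengths(posList))
            list(chrom = ch, pos = gp)
        }
        bins <- GenomicRanges::tileGenome(
            stats::setNames(
                vapply(split(end(refRanges), as.character(seqnames(refRanges))),
                       max, 0),
                unique(as.character(seqnames(refRanges)))[
                    order(unique(as.character(seqnames(refRanges))))]),
            tilewidth = binSize, cut.last.tile.in.chrom = TRUE)
        bins <- bins[IRanges::overlapsAny(bins, refRanges,
                                                ignore.strand = TRUE)]
        countIn <- function(ev) {
            if (!length(ev$pos)) return(integer(length(bins)))
            gr <- GRanges(ev$chrom, IRanges(ev$pos, width = 1L))
            GenomicRanges::countOverlaps(bins, gr, ignore.strand = TRUE)
        }
        snpBin <- countIn(toGenome(snpPos))
        indelBin <- countIn(toGenome(indelPos))
        out$perMb <- data.frame(
            chrom = as.character(seqnames(bins)),
            start = start(bins), end = end(bins),
            snps = snpBin, indels = indelBin, stringsAsFactors = FALSE)
        out$medianSnpsPerMb <- stats::median(snpBin)
        out$medianIndelsPerMb <- stats::median(indelBin)
    }
    out
}

# longest increasing subsequence (indices) of a numeric vector
lisIndices <- function(v) {
    n <- length(v)
    if (!n) return(integer())
    best <- rep(1L, n)
    prev <- rep(0L, n)
    for (i in seq_len(n)) {
        for (j in seq_len(i - 1L)) {
            if (v[j] < v[i] && best[j] + 1L > best[i]) {
                best[i] <- best[j] + 1L
                prev[i] <- j
            }
        }
    }
    i <- which.max(best)
    out <- integer()
    while (i > 0L) { out <- c(i, out); i <- prev[i] }
    out
}

#' Classify alignment blocks into rearrangement categories
#'
#' Rules, per block: \emph{inversion} when the strand is \code{-} and the
#' block lies on its reference chromosome's corresponding query chromosome
#' (correspondence by majority of aligned bases); else \emph{syntenic} when
#' it belongs to the longest chain of blocks collinear in both genomes
#' (longest increasing subsequence on query start within each reference
#' chromosome); else \emph{duplication} when its query interval reciprocally
#' overlaps at least \code{dupOverlap} of another kept block's query
#' interval (so of two copies of one source segment, the one sitting in the
#' collinear backbone keeps its syntenic role and the displaced copy is the
#' duplication); else \emph{translocation}.
#'
#' @param blocks filtered \linkS4class{AlignmentBlocks}.
#' @param dupOverlap reciprocal query-overlap fraction (default 0.5).
#' @return list: \code{blocks} (with classification filled) and
#'   \code{summary} data.frame of per-class count and mean reference block
#'   size in kb.
#' @export
classifyBlocks <- function(blocks, dupOverlap = 0.5) {
    n <- length(blocks)
    cls <- rep(NA_character_, n)
    ref <- refRanges(blocks); qry <- queryRanges(blocks)
    # chromosome correspondence by majority of aligned reference bases
    refChr <- as.character(seqnames(ref)); qryChr <- as.character(seqnames(qry))
    corresp <- vapply(unique(refChr), function(ch) {
        w <- tapply(width(ref)[refChr == ch], qryChr[refChr == ch], sum)
        names(w)[which.max(w)]
    }, "")
    minus <- blockStrand(blocks) == "-"
    onCorresp <- qryChr == corresp[refChr]
    cls[minus & onCorresp] <- "inversion"
    # syntenic chain per reference chromosome among plus-strand blocks on
    # the corresponding chromosome
    for (ch in unique(refChr)) {
        cand <- which(is.na(cls) & refChr == ch & onCorresp & !minus)
        if (length(cand)) {
            cand <- cand[order(start(ref)[cand])]
            chain <- lisIndices(start(qry)[cand])
            cls[cand[chain]] <- "syntenic"
        }
    }
    # off-chain blocks: duplication when another kept block covers the same
    # query interval, else translocation
    rest <- which(is.na(cls))
    if (length(rest)) {
        hits <- GenomicRanges::findOverlaps(qry[rest], qry,
                                            ignore.strand = TRUE)
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        self <- rest[qh] == sh
        qh <- qh[!self]; sh <- sh[!self]
        if (length(qh)) {
            ow <- width(IRanges::pintersect(qry[rest][qh], qry[sh]))
            recip <- ow >= dupOverlap * width(qry[rest][qh]) &
                     ow >= dupOverlap * width(qry[sh])
            cls[rest[unique(qh[recip])]] <- "duplication"
        }
    }
    cls[is.na(cls)] <- "translocation"
    blocks@classification <- cls
    sizes <- width(ref)
    summ <- do.call(rbind, lapply(split(seq_len(n), cls), function(ii)
        data.frame(class = cls[ii[1L]], count = length(ii),
                   meanSizeKb = mean(sizes[ii]) / 1000,
                   stringsAsFactors = FALSE)))
    rownames(summ) <- NULL
    list(blocks = blocks, summary = summ)
}
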