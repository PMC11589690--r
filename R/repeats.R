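#' Windowed repeat density
#'
#' Percent of repeat-derived base pairs per genome window; overlapping hits
#' are merged first so a base counts once.
#'
#' @param hits repeat-hit \code{GRanges} (e.g. from
#'   \code{\link{readRepeatMaskerOut}}).
#' @param seqlengths named chromosome lengths.
#' @param window window width in bp (default 1 Mb).
#' @return \code{GRanges} of windows with a \code{density} column (percent).
#' @export
repeatDensityWindows <- function(hits, seqlengths, window = 1e6) {
    chr <- as.character(seqnames(hits))
    bad <- which(!chr %in% names(seqlengths) | end(hits) > seqlengths[chr] |
                 start(hits) < 1L)
    if (length(bad))
        stop("repeat hit beyond chromosome bounds (hit ", bad[1L], ")")
    windows <- GenomicRanges::tileGenome(seqlengths, tilewidth = window,
                                         cut.last.tile.in.chrom = TRUE)
    merged <- GenomicRanges::reduce(hits, ignore.strand = TRUE)
    hitsW <- GenomicRanges::findOverlaps(merged, windows, ignore.strand = TRUE)
    ow <- width(IRanges::pintersect(merged[S4Vectors::queryHits(hitsW)],
                                    windows[S4Vectors::subjectHits(hitsW)]))
    covered <- rep(0, length(windows))
    tot <- tapply(ow, S4Vectors::subjectHits(hitsW), sum)
    covered[as.integer(names(tot))] <- tot
    mcols(windows)$density <- 100 * covered / width(windows)
    windows
}

#' Compare repeat density inside a region against the rest of the genome
#'
#' Mann-Whitney U test (two-sided, with tie correction and 0.5 continuity
#' correction under the normal approximation; exact enumeration when both
#' sides have at most \code{exactMax} windows).
#'
#' @param density windowed density \code{GRanges} from
#'   \code{\link{repeatDensityWindows}}.
#' @param region a \code{GRanges} region.
#' @param exactMax switch to the exact test at or below this many windows
#'   per side (default 8).
#' @return list: medianInside, medianOutside, U, p.
#' @export
compareRegionDensity <- function(density, region, exactMax = 8L) {
    inside <- IRanges::overlapsAny(density, region,
                                         ignore.strand = TRUE)
    a <- mcols(density)$density[inside]
    b <- mcols(density)$density[!inside]
    if (length(a) < 3L || length(b) < 3L)
        stop("need at least 3 windows inside and outside the region")
    if (length(unique(c(a, b))) == 1L)
        return(list(medianInside = stats::median(a),
                    medianOutside = stats::median(b),
                    U = length(a) * length(b) / 2, p = 1))
    exact <- length(a) <= exactMax && length(b) <= exactMax
    wt <- suppressWarnings(stats::wilcox.test(
        a, b, exact = exact, correct = TRUE, alternative = "two.sided"))
    list(medianInside = stats::median(a), medianOutside = stats::median(b),
         U = unname(wt$statistic), p = wt$p.value)
}

#' Sex-differential repeat enrichment
#'
#' Computes both directional abundance ratios per repeat family and calls a
#' family enriched in a sex when that sex's abundance is at least
#' \code{threshold} times the other's (boundary inclusive).  Families absent
#' from both sexes are skipped with a warning; a zero denominator with a
#' nonzero numerator yields an infinite ratio and an enrichment call.
#'
#' @param tab data.frame with columns \code{family} (and optionally
#'   \code{class}), \code{male} and \code{female}: abundance as percent of
#'   assayed bases (or reads) per genome.
#' @param threshold enrichment threshold (default 1.1).
#' @return data.frame: family, maleFemaleRatio, femaleMaleRatio, call;
#'   sorted by descending maximum ratio.
#' @export
sexEnrichment <- function(tab, threshold = 1.1) {
    stopifnot(all(c("family", "male", "female") %in% names(tab)))
    zero <- tab$male == 0 & tab$female == 0
    if (any(zero)) {
        warning("skipping family with zero abundance in both sexes: ",
                paste(tab$family[zero], collapse = ", "))
        tab <- tab[!zero, , drop = FALSE]
    }
    mf <- ifelse(tab$female > 0, tab$male / tab$female, Inf)
    fm <- ifelse(tab$male > 0, tab$female / tab$male, Inf)
    call <- ifelse(mf >= threshold, "male_enriched",
            ifelse(fm >= threshold, "female_enriched", "none"))
    out <- data.frame(family = tab$family, maleFemaleRatio = mf,
                      femaleMaleRatio = fm, call = call,
                      stringsAsFactors = FALSE)
    out[order(-pmax(out$maleFemaleRatio, out$femaleMaleRatio)), ,
        drop = FALSE]
}

#' Repeat divergence landscape
#'
#' Histogram of repeat abundance by divergence-to-consensus, in 1-percent
#' bins [0,1), [1,2), ..., expressed as percent of assayed genome bases.
#'
#' @param hits repeat-hit \code{GRanges} with a \code{divergence} column.
#' @param genomeBases total assayed bases (denominator).
#' @param binWidth divergence bin width in percent (default 1).
#' @return data.frame: binStart, binEnd, percent.
#' @export
divergenceLandscape <- function(hits, genomeBases, binWidth = 1) {
    stopifnot(genomeBases > 0)
    div <- mcols(hits)$divergence
    if (length(div) && any(div < 0 | div > 100))
        stop("divergence outside [0,100]")
    starts <- seq(0, 100 - binWidth, by = binWidth)
    bin <- pmin(floor(div / binWidth), length(starts) - 1L)
    mass <- rep(0, length(starts))
    if (length(div)) {
        tot <- tapply(width(hits), bin, sum)
        mass[as.integer(names(tot)) + 1L] <- tot
    }
    data.frame(binStart = starts, binEnd = starts + binWidth,
               percent = 100 * mass / genomeBases)
}
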