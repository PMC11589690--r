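#' Hard-filter parameters for genotype calls
#'
#' Defaults follow the usual heuristics for diploid short-read calls: drop
#' sites with QUAL < 30 or depth < 3; heterozygous genotypes need depth >= 4
#' and site QUAL >= twice the dataset mean depth; homozygous genotypes with
#' QUAL < 50 need depth >= 4; sites where any genotype depth exceeds
#' \code{mean + 3 * sqrt(mean)} are treated as likely collapsed repeats or
#' CNVs; sites inside the repeat mask are removed.
#'
#' @param minSiteQual,minDepth rule 1 thresholds (site level).
#' @param minHetDepth rule 2 threshold (het genotypes).
#' @param minHomQual,minHomDepth rule 3 thresholds (hom genotypes).
#' @param hetQualDepthFactor rule 4 multiplier on the mean depth.
#' @param maxDepthSdFactor rule 5 multiplier on sqrt(mean depth).
#' @return a named list of thresholds.
#' @export
filterParams <- function(minSiteQual = 30, minDepth = 3, minHetDepth = 4,
                         minHomQual = 50, minHomDepth = 4,
                         hetQualDepthFactor = 2, maxDepthSdFactor = 3) {
    p <- list(minSiteQual = minSiteQual, minDepth = minDepth,
              minHetDepth = minHetDepth, minHomQual = minHomQual,
              minHomDepth = minHomDepth,
              hetQualDepthFactor = hetQualDepthFactor,
              maxDepthSdFactor = maxDepthSdFactor)
    stopifnot(all(unlist(p) >= 0))
    p
}

#' Variant hard-filter cascade
#'
#' Applies, in order: (1) site QUAL below \code{minSiteQual} or mean
#' genotype depth below \code{minDepth}; (2) any heterozygous genotype with
#' depth below \code{minHetDepth}; (3) site QUAL below \code{minHomQual}
#' with any homozygous genotype depth below \code{minHomDepth}; then, with
#' the dataset mean depth computed over all genotypes at sites passing
#' rules 1-3: (4) heterozygous site with QUAL below
#' \code{hetQualDepthFactor} times the mean depth; (5) maximum genotype
#' depth above \code{mean + maxDepthSdFactor * sqrt(mean)}; (6) overlap
#' with \code{repeatMask}.  A site is removed by the first rule it
#' violates; the result is independent of input order.
#'
#' @param x a \linkS4class{VariantCalls}.
#' @param params see \code{\link{filterParams}}.
#' @param repeatMask optional \code{GRanges} of repeat intervals (rule 6).
#' @return list with elements \code{kept} (a \code{VariantCalls}),
#'   \code{removed} (data.frame of 1-based input row index and the rule
#'   tag), and \code{meanDepth}.
#' @export
filterVariants <- function(x, params = filterParams(), repeatMask = NULL) {
    dp <- assay(x, "DP")
    if (all(is.na(dp)))
        stop("no DP values anywhere; the filter cascade is undefined without depth")
    qual <- siteQual(x)
    het <- isHet(x)
    a <- assay(x, "alleleA"); b <- assay(x, "alleleB")
    hom <- !is.na(a) & !is.na(b) & a == b
    n <- nrow(x)
    reason <- rep(NA_character_, n)
    meanDpSite <- rowMeans(dp, na.rm = TRUE)
    r1 <- (!is.na(qual) & qual < params$minSiteQual) |
        (is.finite(meanDpSite) & meanDpSite < params$minDepth)
    reason[r1] <- "low_qual_or_depth"
    r2 <- rowSums(het & !is.na(dp) & dp < params$minHetDepth) > 0
    reason[is.na(reason) & r2] <- "het_low_depth"
    r3 <- (!is.na(qual) & qual < params$minHomQual) &
        rowSums(hom & !is.na(dp) & dp < params$minHomDepth) > 0
    reason[is.na(reason) & r3] <- "hom_low_qual_depth"
    pass13 <- is.na(reason)
    meanDepth <- mean(dp[pass13, , drop = FALSE], na.rm = TRUE)
    anyHet <- rowSums(het) > 0
    r4 <- anyHet & !is.na(qual) &
        qual < params$hetQualDepthFactor * meanDepth
    reason[is.na(reason) & r4] <- "het_qual_vs_depth"
    maxDp <- suppressWarnings(apply(dp, 1L, max, na.rm = TRUE))
    r5 <- is.finite(maxDp) &
        maxDp > meanDepth + params$maxDepthSdFactor * sqrt(meanDepth)
    reason[is.na(reason) & r5] <- "excess_depth"
    if (!is.null(repeatMask) && length(repeatMask)) {
        r6 <- IRanges::overlapsAny(rowRanges(x), repeatMask,
                                         ignore.strand = TRUE)
        reason[is.na(reason) & r6] <- "repeat_overlap"
    }
    keep <- is.na(reason)
    list(kept = x[keep, ],
         removed = data.frame(index = which(!keep),
                              reason = reason[!keep],
                              stringsAsFactors = FALSE),
         meanDepth = meanDepth)
}
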