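#' Windowed per-sample coverage and heterozygosity
#'
#' Tiles the genome into fixed windows and computes, per sample, (i) mean
#' depth normalized by that sample's genome-wide median window depth (so the
#' autosomal expectation is 1.0) and (ii) heterozygosity, the number of
#' heterozygous calls divided by callable sites in the window.  Callable
#' sites are the bases with nonzero depth in the sample's coverage track.
#'
#' @param coverage either a \code{RangedSummarizedExperiment} with a
#'   \code{depth} assay (tiles x samples) or a named list of \code{GRanges}
#'   coverage tracks with a \code{score} column (bedGraph-style mean depth).
#' @param sex named character vector ("M"/"F") defining the samples to use.
#' @param variants optional \linkS4class{VariantCalls} for heterozygosity;
#'   samples without genotypes get \code{NA} heterozygosity.
#' @param windowSize window width in bp.
#' @param minCallable windows with fewer callable sites get \code{NA}
#'   heterozygosity.
#' @param seqlengths optional named vector; defaults to the coverage seqinfo.
#' @return \code{RangedSummarizedExperiment} with assays \code{coverage}
#'   (normalized), \code{het} and \code{callable}; \code{colData} carries
#'   \code{sex}.
#' @export
windowStats <- function(coverage, sex, variants = NULL, windowSize = 1e5,
                        minCallable = 100, seqlengths = NULL) {
    stopifnot(windowSize > 0)
    samples <- names(sex)
    if (is(coverage, "RangedSummarizedExperiment")) {
        tiles <- rowRanges(coverage)
        d <- assay(coverage, "depth")
        miss <- setdiff(samples, colnames(d))
        if (length(miss))
            stop("no coverage for sample(s): ", paste(miss, collapse = ", "))
        covList <- lapply(samples, function(s) {
            gr <- tiles
            mcols(gr) <- DataFrame(score = d[, s])
            gr
        })
        names(covList) <- samples
    } else {
        miss <- setdiff(samples, names(coverage))
        if (length(miss))
            stop("no coverage for sample(s): ", paste(miss, collapse = ", "))
        covList <- coverage[samples]
    }
    if (is.null(seqlengths)) {
        sl <- GenomeInfoDb::seqlengths(covList[[1L]])
        if (!length(sl) || anyNA(sl)) {
            allcov <- unlist(GRangesList(lapply(covList, function(g) {
                mcols(g) <- NULL
                GenomeInfoDb::seqlevels(g) <- GenomeInfoDb::seqlevelsInUse(g)
                g
            })), use.names = FALSE)
            sl <- vapply(S4Vectors::split(end(allcov), as.character(seqnames(allcov))),
                         max, 0)
        }
        seqlengths <- sl
    }
    windows <- GenomicRanges::tileGenome(seqlengths, tilewidth = windowSize,
                                         cut.last.tile.in.chrom = TRUE)
    nw <- length(windows)
    covMat <- matrix(NA_real_, nw, length(samples),
                     dimnames = list(NULL, samples))
    calMat <- matrix(0, nw, length(samples), dimnames = list(NULL, samples))
    for (s in samples) {
        track <- covList[[s]]
        hits <- GenomicRanges::findOverlaps(track, windows)
        ow <- width(IRanges::pintersect(
            track[S4Vectors::queryHits(hits)],
            windows[S4Vectors::subjectHits(hits)]))
        sc <- mcols(track)$score[S4Vectors::queryHits(hits)]
        raw <- rep(0, nw)
        tot <- tapply(sc * ow, S4Vectors::subjectHits(hits), sum)
        raw[as.integer(names(tot))] <- tot
        raw <- raw / width(windows)
        cal <- rep(0, nw)
        pos <- sc > 0
        if (any(pos)) {
            ct <- tapply(ow[pos], S4Vectors::subjectHits(hits)[pos], sum)
            cal[as.integer(names(ct))] <- ct
        }
        med <- stats::median(raw)
        if (!is.finite(med) || med <= 0)
            stop("sample ", s, ": genome-wide median depth is zero")
        covMat[, s] <- raw / med
        calMat[, s] <- cal
    }
    hetMat <- matrix(NA_real_, nw, length(samples),
                     dimnames = list(NULL, samples))
    if (!is.null(variants)) {
        het <- isHet(variants)
        vcSamples <- intersect(samples, colnames(het))
        hits <- GenomicRanges::findOverlaps(
            GenomicRanges::resize(rowRanges(variants), 1L, fix = "start"),
            windows)
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        for (s in vcSamples) {
            cnt <- rep(0, nw)
            hs <- het[qh, s]
            tt <- tapply(as.numeric(hs), sh, sum)
            cnt[as.integer(names(tt))] <- tt
            hetMat[, s] <- ifelse(calMat[, s] >= minCallable,
                                  cnt / calMat[, s], NA_real_)
        }
    }
    SummarizedExperiment(
        assays = list(coverage = covMat, het = hetMat, callable = calMat),
        rowRanges = windows,
        colData = DataFrame(sex = unname(sex), row.names = samples))
}

#' Per-window male/female contrasts
#'
#' @param ws output of \code{\link{windowStats}}.
#' @return \code{GRanges} of the windows with mean per-sex normalized
#'   coverage and heterozygosity, the F-M coverage difference, the M/F
#'   coverage ratio and the M-F heterozygosity difference.
#' @export
sexDiffTable <- function(ws) {
    sexes <- colData(ws)$sex
    if (sum(sexes == "M") < 1L || sum(sexes == "F") < 1L)
        stop("need at least one sample of each sex")
    cov <- assay(ws, "coverage"); het <- assay(ws, "het")
    covM <- rowMeans(cov[, sexes == "M", drop = FALSE])
    covF <- rowMeans(cov[, sexes == "F", drop = FALSE])
    hetM <- rowMeans(het[, sexes == "M", drop = FALSE], na.rm = TRUE)
    hetF <- rowMeans(het[, sexes == "F", drop = FALSE], na.rm = TRUE)
    gr <- rowRanges(ws)
    mcols(gr) <- DataFrame(
        covM = covM, covF = covF,
        covDiffFM = covF - covM,
        covRatioMF = ifelse(covF > 0, covM / covF, NA_real_),
        hetM = hetM, hetF = hetF, hetDiffMF = hetM - hetF)
    gr
}

#' Flag windows outside the genome-wide confidence band
#'
#' For each contrast (male-female coverage difference; male-female
#' heterozygosity difference) a genome-wide band
#' \code{median +/- z * MAD} is computed (z the two-sided normal quantile for
#' \code{ciLevel}) and windows outside it are flagged high or low.  The
#' robust band keeps the null scale estimate insensitive to the sex-linked
#' windows themselves; on homogeneous noise the expected flagged fraction is
#' \code{1 - ciLevel}.
#'
#' @param sdt output of \code{\link{sexDiffTable}}.
#' @param ciLevel confidence level of the band (default 0.95).
#' @return \code{sdt} with added \code{flagCov} and \code{flagHet} columns
#'   (values \code{cov_low}/\code{cov_high}/\code{het_low}/\code{het_high}/
#'   \code{none}).
#' @export
flagOutlierWindows <- function(sdt, ciLevel = 0.95) {
    if (length(sdt) < 20L)
        stop("need at least 20 windows to estimate the confidence band")
    z <- stats::qnorm(1 - (1 - ciLevel) / 2)
    flagStat <- function(x, low, high) {
        f <- rep("none", length(x))
        v <- x[is.finite(x)]
        if (!length(v)) return(f)
        ctr <- stats::median(v)
        scl <- stats::mad(v)
        if (scl == 0) scl <- stats::sd(v)
        if (!is.finite(scl) || scl == 0) {
            warning("all-constant statistic; no windows flagged")
            return(f)
        }
        f[which(x > ctr + z * scl)] <- high
        f[which(x < ctr - z * scl)] <- low
        f
    }
    mcols(sdt)$flagCov <- flagStat(-mcols(sdt)$covDiffFM, "cov_low", "cov_high")
    mcols(sdt)$flagHet <- flagStat(mcols(sdt)$hetDiffMF, "het_low", "het_high")
    sdt
}

#' Call sex-linked regions from flagged windows
#'
#' Maximal runs of at least \code{minRun} flagged windows (tolerating up to
#' \code{maxGap} unflagged interior windows) become candidate regions, then
#' classified from their pooled evidence: \emph{homogametic}
#' (male-hemizygous) when the mean M/F coverage ratio is at most
#' \code{hemiRatioMax} and male heterozygosity is below female;
#' \emph{heterogametic} (diverged X/Y haplotypes) when the coverage ratio
#' lies in \code{diploidRatio} and male heterozygosity is at least
#' \code{hetExcess} times female.  Candidates fitting neither pattern are
#' dropped with a warning; unflagged genome is implicitly autosomal (see
#' \code{\link{fillAutosomal}}).
#'
#' @param sdt flagged table from \code{\link{flagOutlierWindows}}.
#' @param minRun minimum number of flagged windows in a run.
#' @param maxGap maximum number of unflagged interior windows tolerated.
#' @param hemiRatioMax,diploidRatio,hetExcess classification thresholds.
#' @return \code{GRanges} of called regions with \code{class},
#'   \code{nWindows}, \code{covRatio}, \code{hetM}, \code{hetF} and
#'   \code{hetDiff} columns.
#' @export
callRegions <- function(sdt, minRun = 3L, maxGap = 1L, hemiRatioMax = 0.75,
                        diploidRatio = c(0.85, 1.15), hetExcess = 1.5) {
    if (is.null(mcols(sdt)$flagCov))
        stop("flags not computed; run flagOutlierWindows() first")
    out <- GRanges()
    for (chr in unique(as.character(seqnames(sdt)))) {
        w <- sdt[seqnames(sdt) == chr]
        w <- w[order(start(w))]
        flagged <- mcols(w)$flagCov != "none" | mcols(w)$flagHet != "none"
        idx <- which(flagged)
        if (!length(idx)) next
        # group flagged windows, tolerating <= maxGap unflagged interior ones
        grp <- cumsum(c(1L, diff(idx) > maxGap + 1L))
        for (g in unique(grp)) {
            ii <- idx[grp == g]
            if (length(ii) < minRun) next
            span <- seq(min(ii), max(ii))
            ev <- mcols(w)[span, ]
            covRatio <- mean(ev$covM) / mean(ev$covF)
            hetM <- mean(ev$hetM, na.rm = TRUE)
            hetF <- mean(ev$hetF, na.rm = TRUE)
            hetHigh <- is.finite(hetM) && hetM > 0 &&
                (!is.finite(hetF) || hetM >= hetExcess * hetF)
            cls <- NA_character_
            if (is.finite(covRatio) && covRatio <= hemiRatioMax) {
                if (hetHigh)
                    warning("region on ", chr,
                            ": conflicting evidence (hemizygous coverage but ",
                            "male heterozygosity excess); calling homogametic")
                if (hetHigh || (is.finite(hetF) && hetM < hetF) ||
                    !is.finite(hetF))
                    cls <- "homogametic"
            } else if (is.finite(covRatio) &&
                       covRatio >= diploidRatio[1L] &&
                       covRatio <= diploidRatio[2L] && hetHigh) {
                cls <- "heterogametic"
            }
            if (is.na(cls)) {
                warning("dropping candidate region on ", chr,
                        ": evidence fits neither class (cov ratio ",
                        sprintf("%.2f", covRatio), ")")
                next
            }
            reg <- GRanges(chr, IRanges(min(start(w)[span]),
                                        max(end(w)[span])))
            mcols(reg) <- DataFrame(class = cls, nWindows = length(span),
                                    covRatio = covRatio, hetM = hetM,
                                    hetF = hetF, hetDiff = hetM - hetF)
            suppressWarnings(out <- c(out, reg))
        }
    }
    out
}

#' Region length in megabases
#'
#' @param region \code{GRanges}.
#' @return numeric vector, \code{width / 1e6} (exact; display at 0.1 Mb).
#' @export
regionLengthMb <- function(region) {
    unname(width(region) / 1e6)
}

#' Complete a region call set with the autosomal remainder
#'
#' @param regions called regions from \code{\link{callRegions}}.
#' @param seqlengths named chromosome lengths.
#' @return sorted \code{GRanges} partitioning the genome, uncalled intervals
#'   labelled \code{autosomal}.
#' @export
fillAutosomal <- function(regions, seqlengths) {
    genome <- GRanges(names(seqlengths), IRanges(1L, unname(seqlengths)))
    strip <- regions
    mcols(strip) <- NULL
    rest <- GenomicRanges::setdiff(genome, strip, ignore.strand = TRUE)
    mcols(rest)$class <- if (length(rest)) "autosomal" else character()
    keep <- regions
    mcols(keep) <- DataFrame(class = mcols(regions)$class)
    out <- sort(c(keep, rest), ignore.strand = TRUE)
    names(out) <- NULL
    mcols(out)$name <- mcols(out)$class
    out
}
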