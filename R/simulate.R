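#' Configuration for the synthetic neo-XY population generator
#'
#' Defines the study conditions the generator emulates: a neo-X chromosome
#' carrying (i) a hemizygous XL arm (males have one copy: half coverage,
#' no heterozygous calls) and (ii) a non-recombining stratum where males
#' carry diverged X and Y haplotypes (normal coverage, excess male
#' heterozygosity from fixed X-Y differences), against an autosomal
#' background.
#'
#' @param seed integer; every downstream random draw flows from it.
#' @param genome named integer vector of chromosome lengths (must include
#'   the neo-X).
#' @param stratum \code{GRanges} (length 1) of the sex-linked stratum on the
#'   neo-X.
#' @param xlInterval \code{GRanges} of the hemizygous XL arm, or NULL.
#' @param nMales,nFemales sample counts (>= 1).
#' @param xySnpDivergence per-site probability of a fixed X-Y difference in
#'   the stratum.
#' @param xyIndelRate per-site probability of an X-Y indel (1-10 bp) in the
#'   stratum, placed outside coding sequence.
#' @param polymorphismRate expected per-sample heterozygosity outside sex
#'   linkage (segregating sites are placed at twice this density with
#'   allele frequency 1/2).
#' @param pseudogenizationRate per-gene probability that a stratum gene's Y
#'   copy receives a premature stop (single substitution) or a 1-2 bp
#'   frameshift, with equal probability.
#' @param meanDepth expected per-base coverage (males get half inside XL).
#' @param nGenesStratum,nGenesPar gene counts inside the stratum and
#'   elsewhere.
#' @param geneLengthRange CDS length range in bp (values are rounded to
#'   codons; a terminal stop codon is included).
#' @param repeatConfig data.frame: family, class, malePct, femalePct,
#'   divMean -- per-family target abundance (percent of genome bases) per
#'   sex and mean divergence to consensus.
#' @param blockConfig list of rearranged-block parameters; see
#'   \code{\link{simulateRearrangedBlocks}}.
#' @param covTile tile width (bp) at which Poisson coverage is emitted.
#' @return validated config list.
#' @export
simConfig <- function(seed = 1L,
                      genome = c(neoX = 10e6, chr2 = 5e6),
                      stratum = GRanges("neoX", IRanges(5e6 + 1, 7e6)),
                      xlInterval = GRanges("neoX", IRanges(1, 3e6)),
                      nMales = 4L, nFemales = 4L,
                      xySnpDivergence = 0.01, xyIndelRate = 5e-4,
                      polymorphismRate = 0.001,
                      pseudogenizationRate = 0.4,
                      meanDepth = 20, nGenesStratum = 30L, nGenesPar = 20L,
                      geneLengthRange = c(300, 900),
                      repeatConfig = NULL, blockConfig = NULL,
                      covTile = 1000L) {
    if (is.null(repeatConfig))
        repeatConfig <- data.frame(
            family = c("Gypsy-1", "Copia-1", "LINE-1", "satDNA-1", "satDNA-2"),
            class = c("LTR/Gypsy", "LTR/Copia", "LINE/L2", "Satellite",
                      "Satellite"),
            malePct = c(8, 6, 4, 4.5, 1.0),
            femalePct = c(8, 6, 4, 3.0, 1.1),
            divMean = c(20, 18, 15, 2, 3), stringsAsFactors = FALSE)
    if (is.null(blockConfig)) blockConfig <- list()
    rates <- c(xySnpDivergence, xyIndelRate, polymorphismRate,
               pseudogenizationRate)
    if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]")
    if (nMales < 1L || nFemales < 1L) stop("need at least one of each sex")
    schr <- as.character(seqnames(stratum))[1L]
    if (!schr %in% names(genome)) stop("stratum chromosome not in genome")
    if (end(stratum) > genome[[schr]] || width(stratum) > genome[[schr]])
        stop("stratum longer than its chromosome")
    if (!is.null(xlInterval) && length(xlInterval)) {
        if (sum(width(GenomicRanges::intersect(
                xlInterval, stratum, ignore.strand = TRUE))) > 0)
            stop("xlInterval overlaps the stratum")
        xchr <- as.character(seqnames(xlInterval))[1L]
        if (end(xlInterval) > genome[[xchr]])
            stop("xlInterval longer than its chromosome")
    }
    list(seed = as.integer(seed), genome = genome, stratum = stratum,
         xlInterval = xlInterval, nMales = as.integer(nMales),
         nFemales = as.integer(nFemales),
         xySnpDivergence = xySnpDivergence, xyIndelRate = xyIndelRate,
         polymorphismRate = polymorphismRate,
         pseudogenizationRate = pseudogenizationRate, meanDepth = meanDepth,
         nGenesStratum = as.integer(nGenesStratum),
         nGenesPar = as.integer(nGenesPar),
         geneLengthRange = geneLengthRange, repeatConfig = repeatConfig,
         blockConfig = blockConfig, covTile = as.integer(covTile))
}

#' Generate a ground-truthed synthetic neo-XY population
#'
#' Deterministic given \code{config$seed}; each component draws from its own
#' seed derived from it, so a subset of components reproduces exactly.
#'
#' @param config from \code{\link{simConfig}}.
#' @param components which outputs to generate (reference, genes and
#'   variants are always generated; \code{"repeats"} and \code{"blocks"}
#'   can be dropped to save time).
#' @return a \linkS4class{SimBundle}.
#' @export
simulateNeoXY <- function(config,
                          components = c("repeats", "blocks")) {
    genome <- config$genome
    chroms <- names(genome)
    seqinfo <- GenomeInfoDb::Seqinfo(chroms, unname(genome))
    samples <- c(sprintf("male%02d", seq_len(config$nMales)),
                 sprintf("female%02d", seq_len(config$nFemales)))
    sex <- stats::setNames(rep(c("M", "F"), c(config$nMales, config$nFemales)),
                           samples)
    ## reference -----------------------------------------------------------
    set.seed(stageSeed(config$seed, 1L))
    refRaw <- lapply(genome, function(L) randomDnaRaw(L))
    ## genes ---------------------------------------------------------------
    set.seed(stageSeed(config$seed, 2L))
    genes <- placeGenes(config, refRaw)
    for (i in seq_len(nrow(genes))) {
        g <- genes[i, ]
        seg <- if (g$strand == "+") g$xCds
            else as.character(reverseComplement(DNAString(g$xCds)))
        refRaw[[g$chrom]][g$start:g$end] <- charToRaw(seg)
    }
    ref <- lapply(refRaw, rawToChar)
    ## variants ------------------------------------------------------------
    set.seed(stageSeed(config$seed, 3L))
    v <- simulateVariants(config, ref, genes, samples, sex, seqinfo)
    genes <- v$genes
    ## coverage ------------------------------------------------------------
    set.seed(stageSeed(config$seed, 4L))
    cov <- simulateCoverage(config, samples, sex, seqinfo)
    ## repeats -------------------------------------------------------------
    repeats <- list(male = GRanges(), female = GRanges())
    if ("repeats" %in% components) {
        set.seed(stageSeed(config$seed, 5L))
        repeats <- list(male = placeRepeats(config, "malePct", seqinfo),
                        female = placeRepeats(config, "femalePct", seqinfo))
    }
    ## rearranged blocks ---------------------------------------------------
    blocks <- AlignmentBlocks(GRanges(), GRanges(), character(), numeric())
    blockTruth <- character(); blockAln <- list()
    if ("blocks" %in% components) {
        bl <- simulateRearrangedBlocks(config$blockConfig,
                                       seed = stageSeed(config$seed, 6L))
        blocks <- bl$blocks; blockTruth <- bl$truth
        blockAln <- bl$alignments
    }
    ## truth regions -------------------------------------------------------
    truth <- config$stratum
    mcols(truth) <- DataFrame(class = "heterogametic")
    if (!is.null(config$xlInterval) && length(config$xlInterval)) {
        xl <- config$xlInterval
        mcols(xl) <- DataFrame(class = "homogametic")
        truth <- c(truth, xl)
    }
    rest <- GenomicRanges::setdiff(
        GRanges(chroms, IRanges(1L, unname(genome))),
        truth, ignore.strand = TRUE)
    mcols(rest)$class <- "autosomal"
    truth <- sort(c(truth, rest), ignore.strand = TRUE)
    mcols(truth)$name <- mcols(truth)$class
    GenomeInfoDb::seqlevels(truth) <- chroms
    GenomeInfoDb::seqinfo(truth) <- seqinfo
    grl <- GRangesList(lapply(seq_len(nrow(genes)), function(i) {
        g <- GRanges(genes$chrom[i], IRanges(genes$start[i], genes$end[i]),
                     strand = genes$strand[i], seqinfo = seqinfo)
        mcols(g)$phase <- 0L
        g
    }))
    names(grl) <- genes$gid
    new("SimBundle",
        reference = DNAStringSet(stats::setNames(
            vapply(ref, identity, ""), chroms)),
        truthRegions = truth, variants = v$calls, coverage = cov, sex = sex,
        maleYHap = v$maleYHap, genes = grl,
        geneInfo = DataFrame(gene = genes$gid, chrom = genes$chrom,
                             strand = genes$strand,
                             inStratum = genes$inStratum,
                             status = genes$status, xCds = genes$xCds,
                             yCds = genes$yCds),
        repeats = repeats, blocks = blocks, blockTruth = blockTruth,
        blockAlignments = blockAln, config = config)
}

# ---- internal stages ------------------------------------------------------

placeGenes <- function(config, ref) {
    stratum <- config$stratum
    schr <- as.character(seqnames(stratum))[1L]
    xl <- config$xlInterval
    lens <- round(stats::runif(config$nGenesStratum + config$nGenesPar,
                               config$geneLengthRange[1L],
                               config$geneLengthRange[2L]) / 3) * 3
    lens <- pmax(lens, 30L)
    inStratum <- rep(c(TRUE, FALSE),
                     c(config$nGenesStratum, config$nGenesPar))
    placedS <- lapply(config$genome, function(x) numeric())
    placedE <- placedS
    xlChr <- if (!is.null(xl) && length(xl)) as.character(seqnames(xl))[1L]
        else ""
    chrom <- character(length(lens)); startv <- integer(length(lens))
    for (i in seq_along(lens)) {
        ok <- FALSE
        for (try in 1:200) {
            if (inStratum[i]) {
                ch <- schr
                a <- sample.int(width(stratum) - lens[i] - 100L, 1L) +
                    start(stratum) + 49L
            } else {
                ch <- sample(names(config$genome), 1L,
                             prob = unname(config$genome))
                a <- sample.int(config$genome[[ch]] - lens[i] - 100L, 1L) + 50L
            }
            b <- a + lens[i] - 1L
            clash <- any(a <= placedE[[ch]] + 50L & b >= placedS[[ch]] - 50L)
            if (!inStratum[i]) {
                if (ch == schr && a <= end(stratum) && b >= start(stratum))
                    clash <- TRUE
                if (ch == xlChr && length(xl) &&
                    a <= end(xl)[1L] && b >= start(xl)[1L])
                    clash <- TRUE
            }
            if (!clash) { ok <- TRUE; break }
        }
        if (!ok) stop("cannot place genes without overlap")
        placedS[[ch]] <- c(placedS[[ch]], a)
        placedE[[ch]] <- c(placedE[[ch]], b)
        chrom[i] <- ch; startv[i] <- a
    }
    nCod <- lens / 3L
    sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
    xCds <- vapply(nCod, function(nc) {
        paste0("ATG", paste(sample(sense, nc - 2L, replace = TRUE),
                            collapse = ""), "TAA")
    }, "")
    data.frame(gid = sprintf("g%03d", seq_along(lens)), chrom = chrom,
               start = startv, end = startv + lens - 1L,
               strand = sample(c("+", "-"), length(lens), replace = TRUE),
               inStratum = inStratum, status = "functional",
               xCds = xCds, yCds = xCds, stringsAsFactors = FALSE)
}

# coding-strand position of genomic pos within gene g
codingPos <- function(g, pos) {
    if (g$strand == "+") pos - g$start + 1L else g$end - pos + 1L
}

simulateVariants <- function(config, ref, genes, samples, sex, seqinfo) {
    stratum <- config$stratum
    schr <- as.character(seqnames(stratum))[1L]
    sStart <- start(stratum); sEnd <- end(stratum)
    sLen <- width(stratum)
    genome <- config$genome
    geneGr <- GRanges(genes$chrom, IRanges(genes$start, genes$end))
    refBase <- function(ch, pos, len = 1L)
        substr(ref[[ch]], pos, pos + len - 1L)
    comp <- c(A = "T", C = "G", G = "C", T = "A")

    # fixed X-Y events (all on the stratum chromosome); one occupancy
    # vector keeps every placement O(1)
    evPos <- integer(); evRef <- character(); evAlt <- character()
    vOcc <- logical(genome[[schr]])

    ## X-Y indels (outside genes, inside stratum), placed in one pass
    nInd <- stats::rbinom(1L, sLen, config$xyIndelRate)
    if (nInd > 0L) {
        pos <- sort(sample.int(sLen - 30L, min(nInd, sLen - 30L)) +
                    sStart + 9L)
        pos <- pos[c(TRUE, diff(pos) > 30L)]            # spacing
        nearGene <- IRanges::overlapsAny(
            GRanges(schr, IRanges(pos - 13L, pos + 23L)), geneGr)
        pos <- pos[!nearGene]
        k <- sample.int(10L, length(pos), replace = TRUE)
        insertion <- stats::runif(length(pos)) < 0.5
        for (i in seq_along(pos)) {
            if (insertion[i]) {
                REF <- refBase(schr, pos[i])
                ALT <- paste0(REF, randomDna(k[i]))
                anchor <- pos[i]
            } else {
                anchor <- pos[i] - 1L
                REF <- refBase(schr, anchor, k[i] + 1L)
                ALT <- refBase(schr, anchor)
            }
            evPos <- c(evPos, anchor)
            evRef <- c(evRef, REF); evAlt <- c(evAlt, ALT)
            vOcc[(pos[i] - 1L):(pos[i] + k[i] + 1L)] <- TRUE
        }
    }

    ## X-Y SNPs in the stratum (coding-aware in genes)
    nSnp <- stats::rbinom(1L, sLen, config$xySnpDivergence)
    snpPos <- sStart - 1L + sample.int(sLen, min(nSnp, sLen))
    snpPos <- snpPos[!vOcc[snpPos]]
    # top up positions lost to indel-footprint collisions
    tries <- 0L
    while (length(snpPos) < nSnp && tries < 50L) {
        extra <- sStart - 1L + sample.int(sLen, nSnp - length(snpPos))
        extra <- extra[!vOcc[extra] & !(extra %in% snpPos)]
        snpPos <- c(snpPos, extra)
        tries <- tries + 1L
    }
    geneOf <- rep(NA_integer_, length(snpPos))
    gm <- genes$chrom == schr
    if (any(gm)) {
        gidx <- which(gm)
        hitG <- findInterval(snpPos, sort(genes$start[gidx]))
        # exact containment check per candidate (genes are non-overlapping)
        ordG <- gidx[order(genes$start[gidx])]
        inG <- hitG > 0L & snpPos <= genes$end[ordG][pmax(hitG, 1L)]
        geneOf[inG] <- ordG[hitG[inG]]
    }
    ## non-gene SNPs: fully vectorized
    ng <- which(is.na(geneOf))
    if (length(ng)) {
        p <- snpPos[ng]
        rb <- substring(ref[[schr]], p, p)
        evPos <- c(evPos, p)
        evRef <- c(evRef, rb)
        evAlt <- c(evAlt, randomAlt(rb))
    }
    ## gene SNPs: codon-aware, avoiding stop creation on the Y copy
    gStrand <- genes$strand; gStart <- genes$start; gEnd <- genes$end
    for (i in which(!is.na(geneOf))) {
        p <- snpPos[i]
        gi <- geneOf[i]
        c0 <- if (gStrand[gi] == "+") p - gStart[gi] + 1L else gEnd[gi] - p + 1L
        k <- (c0 - 1L) %/% 3L + 1L
        if (k >= nchar(genes$yCds[gi]) / 3L) next  # leave the terminal stop
        within <- c0 - 3L * (k - 1L)
        codon <- substr(genes$yCds[gi], 3L * k - 2L, 3L * k)
        cur <- substr(codon, within, within)
        altCoding <- pickAltBase(cur, codon, within)
        substr(codon, within, within) <- altCoding
        substr(genes$yCds[gi], 3L * k - 2L, 3L * k) <- codon
        alt <- if (gStrand[gi] == "+") altCoding else comp[[altCoding]]
        evPos <- c(evPos, p)
        evRef <- c(evRef, refBase(schr, p)); evAlt <- c(evAlt, alt)
    }
    vOcc[snpPos] <- TRUE

    ## pseudogenization of stratum genes
    for (gi in which(genes$inStratum)) {
        if (stats::runif(1L) >= config$pseudogenizationRate) next
        g <- genes[gi, ]
        res <- injectDisruption(genes$yCds[gi], g, ref, vOcc, comp)
        if (is.null(res)) next
        genes$yCds[gi] <- res$yCds
        genes$status[gi] <- "pseudogenized"
        evPos <- c(evPos, res$event$pos)
        evRef <- c(evRef, res$event$REF); evAlt <- c(evAlt, res$event$ALT)
        vOcc[res$event$pos:
             (res$event$pos + nchar(res$event$REF) + 1L)] <- TRUE
    }

    ## polymorphic (segregating) sites genome-wide
    totLen <- sum(genome)
    nPoly <- stats::rbinom(1L, totLen, 2 * config$polymorphismRate)
    off <- cumsum(c(0, unname(genome)))[seq_along(genome)]
    names(off) <- names(genome)
    lin <- sample.int(totLen, min(nPoly, totLen))
    pchrom <- names(genome)[findInterval(lin - 1L, cumsum(unname(genome))) + 1L]
    ppos <- lin - off[pchrom]
    freeSel <- !(pchrom == schr & vOcc[ppos])
    pchrom <- pchrom[freeSel]; ppos <- ppos[freeSel]
    # avoid creating stops on the X copy inside coding sequence
    pRef <- character(length(ppos))
    for (ch in unique(pchrom)) {
        ii <- pchrom == ch
        pRef[ii] <- substring(ref[[ch]], ppos[ii], ppos[ii])
    }
    pAlt <- randomAlt(pRef)
    pGene <- rep(NA_integer_, length(ppos))
    for (ch in unique(genes$chrom)) {
        gidx <- which(genes$chrom == ch)
        ii <- which(pchrom == ch)
        if (!length(ii) || !length(gidx)) next
        ordG <- gidx[order(genes$start[gidx])]
        hitG <- findInterval(ppos[ii], genes$start[ordG])
        inG <- hitG > 0L & ppos[ii] <= genes$end[ordG][pmax(hitG, 1L)]
        pGene[ii[inG]] <- ordG[hitG[inG]]
    }
    for (i in which(!is.na(pGene))) {
        gi <- pGene[i]
        c0 <- if (genes$strand[gi] == "+") ppos[i] - genes$start[gi] + 1L
            else genes$end[gi] - ppos[i] + 1L
        k <- (c0 - 1L) %/% 3L + 1L
        if (k >= nchar(genes$xCds[gi]) / 3L) { pAlt[i] <- NA; next }
        within <- c0 - 3L * (k - 1L)
        codon <- substr(genes$xCds[gi], 3L * k - 2L, 3L * k)
        cur <- substr(codon, within, within)
        ac <- pickAltBase(cur, codon, within)
        pAlt[i] <- if (genes$strand[gi] == "+") ac else comp[[ac]]
    }
    keep <- !is.na(pAlt)
    pchrom <- pchrom[keep]; ppos <- ppos[keep]; pAlt <- pAlt[keep]
    pRef <- pRef[keep]

    ## assemble site table
    chrom <- c(rep(schr, length(evPos)), pchrom)
    pos <- c(evPos, ppos)
    REF <- c(evRef, pRef)
    ALT <- c(evAlt, pAlt)
    isFixed <- c(rep(TRUE, length(evPos)), rep(FALSE, length(ppos)))
    n <- length(pos)
    nsamp <- length(samples)
    inStrat <- chrom == schr & pos >= sStart & pos <= sEnd
    xl <- config$xlInterval
    inXl <- if (!is.null(xl) && length(xl))
        chrom == as.character(seqnames(xl))[1L] &
            pos >= start(xl) & pos <= end(xl)
    else rep(FALSE, n)

    a <- matrix(0L, n, nsamp, dimnames = list(NULL, samples))
    b <- a
    polyRows <- which(!isFixed)
    if (length(polyRows)) {
        a[polyRows, ] <- stats::rbinom(length(polyRows) * nsamp, 1L, 0.5)
        b[polyRows, ] <- stats::rbinom(length(polyRows) * nsamp, 1L, 0.5)
    }
    maleCols <- which(sex[samples] == "M")
    # stratum: haplotype 1 = X (polymorphic), haplotype 2 = Y (ref at
    # segregating sites, alt at fixed differences)
    b[inStrat & !isFixed, maleCols] <- 0L
    a[inStrat & isFixed, maleCols] <- 0L
    b[inStrat & isFixed, maleCols] <- 1L
    a[inStrat & isFixed, -maleCols] <- 0L
    b[inStrat & isFixed, -maleCols] <- 0L
    # XL: males are hemizygous; their single allele is reported homozygous
    if (any(inXl))
        b[inXl, maleCols] <- a[inXl, maleCols]
    # permute which emitted haplotype is the Y, per male
    maleYHap <- stats::setNames(sample(1:2, length(maleCols), replace = TRUE),
                                samples[maleCols])
    for (j in seq_along(maleCols)) {
        if (maleYHap[j] == 1L) {
            tmp <- a[inStrat, maleCols[j]]
            a[inStrat, maleCols[j]] <- b[inStrat, maleCols[j]]
            b[inStrat, maleCols[j]] <- tmp
        }
    }
    dp <- matrix(stats::rpois(n * nsamp, config$meanDepth), n, nsamp,
                 dimnames = list(NULL, samples))
    if (any(inXl)) {
        nm <- sum(inXl) * length(maleCols)
        dp[inXl, maleCols] <- stats::rpois(nm, config$meanDepth / 2)
    }
    qual <- pmax(60, round(stats::rnorm(n, 800, 150), 1))
    gq <- matrix(99, n, nsamp, dimnames = list(NULL, samples))
    gr <- GRanges(chrom, IRanges(pos, width = nchar(REF)), seqinfo = seqinfo)
    yAllele <- ifelse(inStrat, ifelse(isFixed, 1L, 0L), NA_integer_)
    o <- order(as.character(seqnames(gr)), start(gr), method = "radix")
    calls <- VariantCalls(gr[o], REF = REF[o], ALT = as.list(ALT[o]),
                          QUAL = qual[o],
                          alleleA = a[o, , drop = FALSE],
                          alleleB = b[o, , drop = FALSE],
                          phased = matrix(TRUE, n, nsamp,
                                          dimnames = list(NULL, samples)),
                          DP = dp[o, , drop = FALSE],
                          GQ = gq[o, , drop = FALSE], sex = sex)
    rowData(calls)$yAllele <- yAllele[o]
    list(calls = calls, genes = genes, maleYHap = maleYHap)
}

# inject one premature stop (single substitution) or 1-2 bp frameshift into
# a Y coding sequence; returns the updated CDS and the genomic event
injectDisruption <- function(yCds, g, ref, vOcc, comp) {
    nCod <- nchar(yCds) / 3L
    isFree <- function(ch, from, to)
        !any(vOcc[max(1L, from):min(length(vOcc), to)])
    refBase <- function(ch, pos, len = 1L)
        substr(ref[[ch]], pos, pos + len - 1L)
    genomicOf <- function(c0) if (g$strand == "+") g$start + c0 - 1L
        else g$end - c0 + 1L
    asFrameshift <- function() {
        for (try in 1:50) {
            k <- sample.int(2L, 1L)
            c0 <- sample.int(nchar(yCds) - 12L, 1L) + 3L
            if (stats::runif(1L) < 0.5) {   # deletion of c0..c0+k-1
                gpos <- range(genomicOf(c0) , genomicOf(c0 + k - 1L))
                anchor <- gpos[1L] - 1L
                if (!isFree(g$chrom, anchor, gpos[2L] + 1L)) next
                REF <- refBase(g$chrom, anchor, gpos[2L] - anchor + 1L)
                ALT <- refBase(g$chrom, anchor)
                yCds <- paste0(substr(yCds, 1L, c0 - 1L),
                               substring(yCds, c0 + k))
            } else {                        # insertion after c0
                s <- randomDna(k)
                anchor <- if (g$strand == "+") genomicOf(c0)
                    else genomicOf(c0) - 1L
                if (!isFree(g$chrom, anchor, anchor + 1L)) next
                REF <- refBase(g$chrom, anchor)
                insG <- if (g$strand == "+") s
                    else as.character(reverseComplement(DNAString(s)))
                ALT <- paste0(REF, insG)
                yCds <- paste0(substr(yCds, 1L, c0), s,
                               substring(yCds, c0 + 1L))
            }
            return(list(yCds = yCds,
                        event = list(chrom = g$chrom, pos = anchor,
                                     REF = REF, ALT = ALT)))
        }
        NULL
    }
    if (stats::runif(1L) < 0.5) {
        # premature stop by a single substitution
        cands <- list()
        for (k in 2:(nCod - 1L)) {
            codon <- substr(yCds, 3L * k - 2L, 3L * k)
            for (p in 1:3) for (bb in setdiff(c("A", "C", "G", "T"),
                                              substr(codon, p, p))) {
                cand <- codon
                substr(cand, p, p) <- bb
                if (isStopCodon(cand))
                    cands[[length(cands) + 1L]] <- c(k, p, bb)
            }
        }
        if (length(cands)) {
            for (try in seq_len(min(50L, length(cands)))) {
                pick <- cands[[sample.int(length(cands), 1L)]]
                k <- as.integer(pick[1L]); p <- as.integer(pick[2L])
                bb <- pick[3L]
                c0 <- 3L * (k - 1L) + p
                gpos <- genomicOf(c0)
                if (!isFree(g$chrom, gpos, gpos)) next
                codon <- substr(yCds, 3L * k - 2L, 3L * k)
                substr(codon, p, p) <- bb
                substr(yCds, 3L * k - 2L, 3L * k) <- codon
                alt <- if (g$strand == "+") bb else comp[[bb]]
                return(list(yCds = yCds,
                            event = list(chrom = g$chrom, pos = gpos,
                                         REF = refBase(g$chrom, gpos),
                                         ALT = alt)))
            }
        }
    }
    asFrameshift()
}

simulateCoverage <- function(config, samples, sex, seqinfo) {
    tiles <- GenomicRanges::tileGenome(
        stats::setNames(unname(config$genome), names(config$genome)),
        tilewidth = config$covTile, cut.last.tile.in.chrom = TRUE)
    GenomeInfoDb::seqinfo(tiles) <- seqinfo
    nt <- length(tiles)
    lam <- matrix(config$meanDepth, nt, length(samples),
                  dimnames = list(NULL, samples))
    xl <- config$xlInterval
    if (!is.null(xl) && length(xl)) {
        hemiFrac <- rep(0, nt)
        hit <- GenomicRanges::findOverlaps(tiles, xl)
        qh <- S4Vectors::queryHits(hit)
        hemiFrac[qh] <- width(IRanges::pintersect(
            tiles[qh], xl[S4Vectors::subjectHits(hit)])) / width(tiles)[qh]
        for (s in samples[sex[samples] == "M"])
            lam[, s] <- config$meanDepth * (1 - hemiFrac / 2)
    }
    w <- width(tiles)
    depth <- matrix(stats::rpois(nt * length(samples), w * lam) / w, nt,
                    dimnames = list(NULL, samples))
    SummarizedExperiment(assays = list(depth = depth), rowRanges = tiles,
                         colData = DataFrame(sex = unname(sex[samples]),
                                             row.names = samples))
}

placeRepeats <- function(config, pctCol, seqinfo) {
    rc <- config$repeatConfig
    frac <- sum(rc[[pctCol]]) / 100
    hits <- list()
    for (ch in names(config$genome)) {
        L <- config$genome[[ch]]
        approxN <- ceiling(L * frac / 1000) + 10L
        lens <- round(stats::runif(approxN, 500, 1500))
        gaps <- round(lens * (1 / frac - 1) * stats::runif(approxN, 0.5, 1.5))
        starts <- cumsum(c(1L, (lens + gaps)[-approxN]))
        keep <- starts + lens - 1L <= L
        hits[[ch]] <- GRanges(ch, IRanges(starts[keep],
                                          width = lens[keep]))
    }
    gr <- unlist(GRangesList(hits), use.names = FALSE)
    fam <- sample(rc$family, length(gr), replace = TRUE,
                  prob = rc[[pctCol]])
    i <- match(fam, rc$family)
    mcols(gr)$family <- fam
    mcols(gr)$class <- rc$class[i]
    mcols(gr)$divergence <- pmin(100, pmax(
        0, stats::rnorm(length(gr), rc$divMean[i], 0.75)))
    GenomeInfoDb::seqlevels(gr) <- names(config$genome)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
    gr
}

#' Truth gametolog pairs of a simulated bundle
#'
#' The generator's own X and Y coding sequences for the stratum genes,
#' packaged as a \linkS4class{GametologPairSet} (useful as ground truth for
#' divergence and pseudogene scoring).
#'
#' @param bundle a \linkS4class{SimBundle}.
#' @param stratumOnly keep only stratum genes (default TRUE).
#' @return a \linkS4class{GametologPairSet}.
#' @export
truthGametologPairs <- function(bundle, stratumOnly = TRUE) {
    gi <- bundle@geneInfo
    if (stratumOnly) gi <- gi[gi$inStratum, , drop = FALSE]
    new("GametologPairSet", geneId = gi$gene,
        xSeq = DNAStringSet(stats::setNames(gi$xCds, paste0(gi$gene, "_X"))),
        ySeq = DNAStringSet(stats::setNames(gi$yCds, paste0(gi$gene, "_Y"))),
        assignment = ifelse(gi$inStratum, "sex-linked", "PAR"))
}

#' Write a simulated bundle to disk
#'
#' Emits ref.fa, truth.bed, variants.vcf, coverage/<sample>.bedgraph,
#' genes.gff3, repeats.male.out / repeats.female.out, blocks.paf, blocks.fa
#' and sex.tsv, all through the package's readers' counterparts.
#'
#' @param bundle a \linkS4class{SimBundle}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimBundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeXStringSet(bundle@reference, file.path(dir, "ref.fa"))
    writeBed(bundle@truthRegions, file.path(dir, "truth.bed"))
    writeVariantVcf(bundle@variants, file.path(dir, "variants.vcf"))
    writeCoverageDir(bundle@coverage, file.path(dir, "coverage"))
    writeGeneModels(bundle@genes, file.path(dir, "genes.gff3"),
                    geneMeta = bundle@geneInfo[, "status", drop = FALSE])
    writeRepeatMaskerOut(bundle@repeats$male,
                         file.path(dir, "repeats.male.out"))
    writeRepeatMaskerOut(bundle@repeats$female,
                         file.path(dir, "repeats.female.out"))
    if (length(bundle@blocks)) {
        writePaf(bundle@blocks, file.path(dir, "blocks.paf"))
        seqs <- unlist(lapply(seq_along(bundle@blockAlignments), function(i) {
            al <- bundle@blockAlignments[[i]]
            stats::setNames(gsub("-", "", c(al[[1L]], al[[2L]]), fixed = TRUE),
                            paste0("block", i, c("_ref", "_qry")))
        }))
        writeXStringSet(DNAStringSet(seqs), file.path(dir, "blocks.fa"))
    }
    writeSexLabels(bundle@sex, file.path(dir, "sex.tsv"))
    invisible(dir)
}
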