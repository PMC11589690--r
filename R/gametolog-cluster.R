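#' Build the phased haplotype matrix for a candidate region
#'
#' Takes the sites of \code{x} falling in \code{region} and splits each
#' sample's genotypes into its two haplotype rows.  Male heterozygous
#' genotypes must be phased (the X/Y separation below is meaningless
#' otherwise); unphased homozygous genotypes are accepted since their
#' haplotype split is unambiguous.
#'
#' @param x a \linkS4class{VariantCalls} with a \code{sex} column.
#' @param region a length-1 \code{GRanges}.
#' @return a \linkS4class{HaplotypeMatrix}.
#' @export
haplotypeMatrix <- function(x, region) {
    stopifnot(length(region) == 1L)
    sex <- sampleSex(x)
    if (is.null(sex)) stop("x carries no sample sex column")
    keep <- IRanges::overlapsAny(rowRanges(x), region,
                                       ignore.strand = TRUE)
    x <- x[keep, ]
    a <- assay(x, "alleleA"); b <- assay(x, "alleleB")
    ph <- assay(x, "phased")
    het <- isHet(x)
    badPhase <- het & !ph & matrix(sex == "M", nrow(x), ncol(x), byrow = TRUE)
    if (any(badPhase, na.rm = TRUE)) {
        j <- which(colSums(badPhase, na.rm = TRUE) > 0)[1L]
        stop("unphased heterozygous male genotype in region (sample ",
             colnames(x)[j], "); phase the input first")
    }
    samples <- colnames(x)
    alleles <- matrix(NA_integer_, 2L * length(samples), nrow(x))
    rn <- character(2L * length(samples))
    for (j in seq_along(samples)) {
        alleles[2L * j - 1L, ] <- a[, j]
        alleles[2L * j, ] <- b[, j]
        rn[c(2L * j - 1L, 2L * j)] <- paste0(samples[j], "_", 1:2)
    }
    rownames(alleles) <- rn
    new("HaplotypeMatrix", region = region, sites = rowRanges(x),
        alleles = alleles, sample = rep(samples, each = 2L),
        hap = rep(1:2, length(samples)),
        sex = rep(unname(sex[samples]), each = 2L))
}

#' Cluster phased haplotypes and identify the Y cluster
#'
#' Pairwise haplotype distance is the mismatch fraction over sites where
#' both haplotypes are called (at least \code{minSites} shared sites,
#' else the pair is unusable).  Average-linkage hierarchical clustering is
#' cut into two clusters.  The Y-cluster criterion: one cluster contains
#' exactly one haplotype from every male and no female haplotype.  The
#' separation score is the mean between-cluster over mean within-cluster
#' distance (Inf when both clusters are internally identical).  Status is
#' \code{assigned} when the criterion holds and separation is at least
#' \code{minSeparation}; \code{ambiguous} when the criterion fails;
#' \code{rejected} when there is no divergence to cluster on or separation
#' is too low.
#'
#' @param hm a \linkS4class{HaplotypeMatrix}.
#' @param minSites minimum shared called sites per haplotype pair (and
#'   minimum total sites).
#' @param minSeparation minimum between/within distance ratio.
#' @return a \linkS4class{GametologAssignment}.
#' @export
clusterHaplotypes <- function(hm, minSites = 20L, minSeparation = 3) {
    m <- hm@alleles
    if (ncol(m) < minSites)
        stop("fewer than ", minSites, " sites in region")
    n <- nrow(m)
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            ok <- !is.na(m[i, ]) & !is.na(m[j, ])
            if (sum(ok) < minSites) {
                D[i, j] <- D[j, i] <- NA_real_
            } else {
                D[i, j] <- D[j, i] <- mean(m[i, ok] != m[j, ok])
            }
        }
    }
    if (anyNA(D))
        stop("haplotype pair(s) share fewer than ", minSites,
             " called sites; distance undefined")
    if (all(D == 0))
        return(new("GametologAssignment", region = hm@region,
                   yHaplotype = integer(), separation = 0,
                   status = "rejected"))
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    cl <- stats::cutree(hc, k = 2L)
    within <- D[outer(cl, cl, "==") & upper.tri(D)]
    between <- D[outer(cl, cl, "!=") & upper.tri(D)]
    separation <- if (length(within) == 0L || mean(within) == 0) Inf
        else mean(between) / mean(within)
    males <- unique(hm@sample[hm@sex == "M"])
    status <- "ambiguous"
    yHap <- integer()
    for (k in 1:2) {
        rows <- which(cl == k)
        if (any(hm@sex[rows] == "F")) next
        smp <- hm@sample[rows]
        if (length(rows) == length(males) && setequal(smp, males) &&
            !anyDuplicated(smp)) {
            yHap <- stats::setNames(hm@hap[rows][match(males, smp)], males)
            status <- "assigned"
            break
        }
    }
    if (status == "assigned" && separation < minSeparation) {
        status <- "rejected"
        yHap <- integer()
    }
    new("GametologAssignment", region = hm@region, yHaplotype = yHap,
        separation = separation, status = status)
}

#' Haploid regenotyping of an assigned region
#'
#' Splits each male's phased genotype into its X and Y calls using the
#' cluster assignment; females contribute both haplotypes to the X panel.
#' Missing genotypes stay missing.
#'
#' @param assignment an assigned \linkS4class{GametologAssignment}.
#' @param x the \linkS4class{VariantCalls} the assignment was derived from
#'   (only sites inside the assignment region are used).
#' @return list of two haploid \linkS4class{VariantCalls}: \code{x} over all
#'   samples' X haplotypes (females as \code{<sample>_1}/\code{_2} columns)
#'   and \code{y} over the males' Y haplotypes.
#' @export
regenotypeHaploid <- function(assignment, x) {
    if (assignment@status != "assigned")
        stop("region not assigned (status ", assignment@status, ")")
    sex <- sampleSex(x)
    keep <- IRanges::overlapsAny(rowRanges(x), assignment@region,
                                       ignore.strand = TRUE)
    x <- x[keep, ]
    a <- assay(x, "alleleA"); b <- assay(x, "alleleB")
    dp <- assay(x, "DP"); gq <- assay(x, "GQ")
    males <- names(assignment@yHaplotype)
    females <- colnames(x)[sex == "F"]
    yHap <- assignment@yHaplotype
    pick <- function(sample, hap) if (hap == 1L) a[, sample] else b[, sample]
    xCols <- c(stats::setNames(lapply(males, function(s)
                   pick(s, 3L - yHap[[s]])), males),
               stats::setNames(lapply(females, function(s) pick(s, 1L)),
                   paste0(females, "_1")),
               stats::setNames(lapply(females, function(s) pick(s, 2L)),
                   paste0(females, "_2")))
    xMat <- do.call(cbind, xCols)
    xDp <- cbind(dp[, males, drop = FALSE],
                 dp[, females, drop = FALSE],
                 dp[, females, drop = FALSE])
    colnames(xDp) <- colnames(xMat)
    yMat <- vapply(males, function(s) pick(s, yHap[[s]]),
                   integer(nrow(x)))
    if (nrow(x) == 1L) yMat <- matrix(yMat, nrow = 1L,
                                      dimnames = list(NULL, males))
    gr <- rowRanges(x)
    mcols(gr) <- NULL
    haploid <- function(mat, dpm) VariantCalls(
        gr, REF = refAllele(x), ALT = altAlleles(x), QUAL = siteQual(x),
        alleleA = mat, DP = dpm)
    list(x = haploid(xMat, xDp),
         y = haploid(yMat, dp[, males, drop = FALSE]))
}
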