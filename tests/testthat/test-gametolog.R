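test_that("the filter cascade removes exactly the crafted offenders", {
    x <- craftedCascade12()
    # run it through VCF text to exercise the real input path
    f <- tempfile(fileext = ".vcf")
    writeVariantVcf(x, f)
    y <- readVariantVcf(f, sex = c(s1 = "M", s2 = "F"))
    mask <- GRanges("chr1", IRanges(6900, 7100))
    res <- filterVariants(y, repeatMask = mask)
    expect_equal(res$meanDepth, 21)
    expect_equal(res$removed$index, 1:7)
    expect_equal(res$removed$reason,
                 c("low_qual_or_depth", "low_qual_or_depth", "het_low_depth",
                   "hom_low_qual_depth", "het_qual_vs_depth", "excess_depth",
                   "repeat_overlap"))
    expect_equal(nrow(res$kept), 5L)
    expect_equal(start(rowRanges(res$kept)), seq(8000L, 12000L, 1000L))
})

test_that("filtering is independent of record order", {
    x <- craftedCascade12()
    mask <- GRanges("chr1", IRanges(6900, 7100))
    set.seed(1)
    perm <- sample(nrow(x))
    a <- filterVariants(x, repeatMask = mask)
    b <- filterVariants(x[perm, ], repeatMask = mask)
    expect_equal(sort(start(rowRanges(a$kept))), sort(start(rowRanges(b$kept))))
    expect_equal(a$meanDepth, b$meanDepth)
    ra <- a$removed$reason[order(a$removed$index)]
    rb <- b$removed$reason[order(perm[b$removed$index])]
    expect_equal(ra, rb)
})

test_that("filtering requires depth information", {
    x <- makeCalls("chr1", 1L, "A", list("T"), 99,
                   gtA = cbind(s = 0L), gtB = cbind(s = 1L),
                   DP = cbind(s = NA_integer_))
    expect_error(filterVariants(x), "DP")
})

# a small crafted haplotype scenario: 3 males with a shared Y haplotype,
# 2 females, 30 sites
craftedHaplotypes <- function(divergent = TRUE, leak = FALSE) {
    nSites <- 30L
    samples <- c(m1 = "M", m2 = "M", m3 = "M", f1 = "F", f2 = "F")
    set.seed(8)
    yHapTruth <- c(m1 = 1L, m2 = 2L, m3 = 1L)
    ySites <- if (divergent) seq(1, 29, 2) else integer()
    a <- b <- matrix(0L, nSites, length(samples),
                     dimnames = list(NULL, names(samples)))
    for (m in names(yHapTruth)) {
        yAll <- integer(nSites); yAll[ySites] <- 1L
        if (yHapTruth[[m]] == 1L) { a[, m] <- yAll } else { b[, m] <- yAll }
    }
    if (leak) b[, "f1"] <- { z <- integer(nSites); z[ySites] <- 1L; z }
    x <- makeCalls("chr1", seq_len(nSites) * 100L, rep("A", nSites),
                   rep(list("T"), nSites), rep(99, nSites),
                   gtA = a, gtB = b,
                   DP = matrix(20L, nSites, length(samples),
                               dimnames = list(NULL, names(samples))),
                   sex = samples)
    list(calls = x, truth = yHapTruth)
}

test_that("haplotype clustering identifies the Y cluster from phased calls", {
    cr <- craftedHaplotypes()
    region <- GRanges("chr1", IRanges(1, 5000))
    hm <- haplotypeMatrix(cr$calls, region)
    as1 <- clusterHaplotypes(hm, minSites = 20)
    expect_equal(as1@status, "assigned")
    expect_equal(as1@yHaplotype[names(cr$truth)], cr$truth)
    expect_gte(as1@separation, 3)
})

test_that("clustering rejects identical haplotypes and flags female leakage", {
    cr0 <- craftedHaplotypes(divergent = FALSE)
    region <- GRanges("chr1", IRanges(1, 5000))
    hm0 <- haplotypeMatrix(cr0$calls, region)
    expect_equal(clusterHaplotypes(hm0, minSites = 20)@status, "rejected")

    crL <- craftedHaplotypes(leak = TRUE)
    hmL <- haplotypeMatrix(crL$calls, region)
    expect_equal(clusterHaplotypes(hmL, minSites = 20)@status, "ambiguous")

    expect_error(clusterHaplotypes(hm0, minSites = 50), "50")
})

test_that("clustering is invariant to sample order and haplotype swaps", {
    cr <- craftedHaplotypes()
    region <- GRanges("chr1", IRanges(1, 5000))
    base <- clusterHaplotypes(haplotypeMatrix(cr$calls, region))
    # permute samples
    perm <- cr$calls[, c("f2", "m2", "m1", "f1", "m3")]
    as2 <- clusterHaplotypes(haplotypeMatrix(perm, region))
    expect_equal(as2@status, "assigned")
    expect_equal(as2@yHaplotype[names(base@yHaplotype)], base@yHaplotype)
    # swap the two haplotype rows of one male
    sw <- cr$calls
    a <- assay(sw, "alleleA"); b <- assay(sw, "alleleB")
    tmp <- a[, "m1"]; a[, "m1"] <- b[, "m1"]; b[, "m1"] <- tmp
    assays(sw)$alleleA <- a; assays(sw)$alleleB <- b
    as3 <- clusterHaplotypes(haplotypeMatrix(sw, region))
    expect_equal(as3@status, "assigned")
    expect_equal(unname(as3@yHaplotype["m1"]), 3L - unname(base@yHaplotype["m1"]))
    expect_equal(as3@yHaplotype[c("m2", "m3")], base@yHaplotype[c("m2", "m3")])
})

test_that("unphased male heterozygotes are refused", {
    cr <- craftedHaplotypes()
    x <- cr$calls
    ph <- assay(x, "phased"); ph[1, "m1"] <- FALSE
    assays(x)$phased <- ph
    expect_error(haplotypeMatrix(x, GRanges("chr1", IRanges(1, 5000))),
                 "unphased")
})

test_that("haploid regenotyping maps phased genotypes onto X and Y panels", {
    samples <- c(m = "M", f = "F")
    x <- makeCalls("chr1", c(100L, 200L, 300L), rep("A", 3),
                   rep(list("T"), 3), rep(99, 3),
                   gtA = cbind(m = c(0L, 1L, NA), f = c(0L, 1L, 0L)),
                   gtB = cbind(m = c(1L, 1L, NA), f = c(1L, 0L, 0L)),
                   DP = matrix(20L, 3, 2, dimnames = list(NULL, c("m", "f"))),
                   sex = samples)
    asg <- new("GametologAssignment",
               region = GRanges("chr1", IRanges(1, 1000)),
               yHaplotype = c(m = 2L), separation = Inf, status = "assigned")
    hap <- regenotypeHaploid(asg, x)
    # male GT 0|1 with haplotype 2 = Y: X call 0, Y call 1; 1|1 -> both 1
    expect_equal(unname(assay(hap$y, "alleleA")[, "m"]), c(1L, 1L, NA))
    expect_equal(unname(assay(hap$x, "alleleA")[, "m"]), c(0L, 1L, NA))
    expect_equal(unname(assay(hap$x, "alleleA")[, "f_1"]), c(0L, 1L, 0L))
    expect_equal(unname(assay(hap$x, "alleleA")[, "f_2"]), c(1L, 0L, 0L))
    # haploid panels have no second allele
    expect_true(all(is.na(assay(hap$y, "alleleB"))))
    # refuse unassigned regions
    asg@status <- "rejected"
    expect_error(regenotypeHaploid(asg, x), "not assigned")
})

test_that("end-to-end on simulation: Y assignment and haploid calls match truth", {
    cfg <- smallConfig(61)
    b <- simulateNeoXY(cfg, components = character())
    f <- filterVariants(b@variants)
    hm <- haplotypeMatrix(f$kept, cfg$stratum)
    asg <- clusterHaplotypes(hm)
    expect_equal(asg@status, "assigned")
    expect_equal(asg@yHaplotype[names(b@maleYHap)], b@maleYHap)
    hap <- regenotypeHaploid(asg, f$kept)
    keep <- IRanges::overlapsAny(rowRanges(f$kept), cfg$stratum)
    truthY <- rowData(f$kept)$yAllele[keep]
    yCalls <- assay(hap$y, "alleleA")
    expect_true(all(yCalls == truthY))
})

test_that("gametolog pairs reconstruct the simulated sequences", {
    cfg <- smallConfig(62)
    b <- simulateNeoXY(cfg, components = character())
    hm <- haplotypeMatrix(b@variants, cfg$stratum)
    asg <- clusterHaplotypes(hm)
    hap <- regenotypeHaploid(asg, b@variants)
    regs <- b@truthRegions[mcols(b@truthRegions)$class == "heterogametic"]
    pairs <- extractGametologPairs(hap, b@reference, b@genes, regs)
    expect_equal(length(pairs), length(b@genes))
    sl <- pairs@assignment == "sex-linked"
    expect_equal(sort(pairs@geneId[sl]),
                 sort(b@geneInfo$gene[b@geneInfo$inStratum]))
    truth <- truthGametologPairs(b)
    m <- match(truth@geneId, pairs@geneId)
    for (i in seq_along(truth@geneId)) {
        expect_identical(as.character(pairs@ySeq[[m[i]]]),
                         as.character(truth@ySeq[[i]]))
    }
    # PAR sequences keep the reference length (no fixed indels outside the
    # stratum)
    par <- which(!sl)
    lens <- vapply(par, function(j) nchar(as.character(pairs@ySeq[[j]])), 0)
    expect_equal(lens, unname(width(unlist(range(b@genes))))[
        match(pairs@geneId[par], names(b@genes))])
})

test_that("genes straddling a region boundary are conservatively PAR", {
    genes <- GRangesList(g1 = GRanges("neoX", IRanges(950, 1300),
                                      strand = "+", phase = 0L))
    regions <- GRanges("neoX", IRanges(1000, 5000))
    mcols(regions)$class <- "heterogametic"
    ref <- DNAStringSet(c(neoX = paste(rep("ACGT", 2000), collapse = "")))
    hap <- list(
        x = makeCalls("neoX", 1L, "A", list("T"), 99, gtA = cbind(s = 0L),
                      gtB = cbind(s = NA_integer_), DP = cbind(s = 20L)),
        y = makeCalls("neoX", 1L, "A", list("T"), 99, gtA = cbind(s = 0L),
                      gtB = cbind(s = NA_integer_), DP = cbind(s = 20L)))
    expect_warning(p <- extractGametologPairs(hap, ref, genes, regions),
                   "boundary")
    expect_equal(p@assignment, "PAR")
})
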