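test_that("the generator is deterministic given the seed", {
    cfg <- smallConfig(101)
    b1 <- simulateNeoXY(cfg, components = character())
    b2 <- simulateNeoXY(cfg, components = character())
    expect_identical(as.character(b1@reference), as.character(b2@reference))
    expect_identical(assay(b1@variants, "alleleA"), assay(b2@variants, "alleleA"))
    expect_identical(assay(b1@coverage, "depth"), assay(b2@coverage, "depth"))
    d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
    writeSimBundle(b1, d1); writeSimBundle(b2, d2)
    for (f in c("variants.vcf", "truth.bed", "genes.gff3", "ref.fa"))
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))))
})

test_that("male heterozygosity in the stratum matches the binomial expectation", {
    cfg <- smallConfig(7)   # divergence 0.01, polymorphism 0.001
    b <- simulateNeoXY(cfg, components = character())
    v <- b@variants
    inStrat <- IRanges::overlapsAny(rowRanges(v), cfg$stratum)
    het <- isHet(v)
    L <- width(cfg$stratum)
    p <- cfg$xySnpDivergence + cfg$polymorphismRate
    # fixed indels also present as heterozygous male sites on top of p
    isIndel <- nchar(refAllele(v)) > 1L |
        vapply(as.list(altAlleles(v)), function(a) any(nchar(a) > 1L), TRUE)
    nInd <- sum(inStrat & isIndel)
    for (s in names(b@sex)[b@sex == "M"]) {
        k <- sum(het[inStrat, s])
        expect_lt(abs(k - (L * p + nInd)), 3 * sqrt(L * p * (1 - p)))
    }
    # female heterozygosity in the stratum is only the polymorphism
    for (s in names(b@sex)[b@sex == "F"]) {
        k <- sum(het[inStrat, s])
        pf <- cfg$polymorphismRate
        expect_lt(abs(k - L * pf), 4 * sqrt(L * pf))
    }
})

test_that("zero X-Y divergence leaves the sexes indistinguishable", {
    cfg <- smallConfig(5, xySnpDivergence = 0, xyIndelRate = 0,
                       pseudogenizationRate = 0)
    cfg$xlInterval <- NULL
    b <- simulateNeoXY(cfg, components = character())
    ws <- windowStats(b@coverage, b@sex, variants = b@variants,
                      windowSize = 1e5)
    sdt <- sexDiffTable(ws)
    tt <- t.test(mcols(sdt)$hetM, mcols(sdt)$hetF, paired = TRUE)
    expect_gt(tt$p.value, 0.001)
    expect_lt(abs(mean(mcols(sdt)$hetDiffMF)), 3e-4)
})

test_that("male coverage halves inside the hemizygous XL arm", {
    cfg <- smallConfig(13)
    b <- simulateNeoXY(cfg, components = character())
    tiles <- rowRanges(b@coverage)
    inXl <- IRanges::overlapsAny(tiles, cfg$xlInterval)
    d <- assay(b@coverage, "depth")
    males <- names(b@sex)[b@sex == "M"]
    females <- names(b@sex)[b@sex == "F"]
    ratio <- mean(d[inXl, males]) / mean(d[inXl, females])
    expect_lt(abs(ratio - 0.5), 0.02)
    expect_lt(abs(mean(d[!inXl, males]) / mean(d[!inXl, females]) - 1), 0.02)
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(genome = c(neoX = 1e6),
                           stratum = GRanges("neoX", IRanges(1, 2e6)),
                           xlInterval = NULL),
                 "longer than its chromosome")
    expect_error(simConfig(xySnpDivergence = 1.5), "rates")
    expect_error(simConfig(nMales = 0), "each sex")
    expect_error(simConfig(genome = c(neoX = 10e6),
                           stratum = GRanges("neoX", IRanges(1e6, 3e6)),
                           xlInterval = GRanges("neoX", IRanges(1, 2e6))),
                 "overlaps")
})

test_that("rearranged block sets carry the requested truth labels", {
    bl <- simulateRearrangedBlocks(list(nInversions = 2L,
                                        nTranslocations = 0L,
                                        nDuplications = 1L), seed = 4)
    tab <- table(bl$truth)
    expect_equal(unname(tab["inversion"]), 2L)
    expect_equal(unname(tab["duplication"]), 1L)
    expect_false("translocation" %in% names(tab))
    expect_equal(sum(bl$truth == "syntenic"), length(bl$truth) - 3L)

    # zero events: everything syntenic at identity 100
    bl0 <- simulateRearrangedBlocks(list(nInversions = 0L,
                                         nTranslocations = 0L,
                                         nDuplications = 0L,
                                         snpRate = 0, indelRate = 0),
                                    seed = 4)
    expect_true(all(bl0$truth == "syntenic"))
    expect_true(all(blockIdentity(bl0$blocks) == 100))
    expect_true(all(blockStrand(bl0$blocks) == "+"))
})

test_that("per-block SNP load matches the Poisson expectation", {
    bl <- simulateRearrangedBlocks(list(snpRate = 1e-3), seed = 8)
    cv <- countBlockVariants(bl$alignments)
    lam <- bl$expectedSnps
    expect_lt(abs(cv$totalSnps - lam), 3 * sqrt(lam) + 0.01 * lam)
})

test_that("overlapping event requests fail loudly", {
    expect_error(simulateRearrangedBlocks(
        list(ancestralLength = 1e5, nInversions = 4L, nTranslocations = 4L,
             nDuplications = 2L, eventSizeRange = c(2e4, 3e4)), seed = 1),
        "overlap")
})

test_that("repeat placement hits the per-sex abundance targets", {
    cfg <- smallConfig(23)
    b <- simulateNeoXY(cfg, components = "repeats")
    tot <- sum(cfg$genome)
    for (sx in c("male", "female")) {
        pctCol <- paste0(sx, "Pct")
        target <- sum(cfg$repeatConfig[[pctCol]])
        got <- 100 * sum(width(b@repeats[[sx]])) / tot
        expect_lt(abs(got - target), 2)
        perFam <- 100 * tapply(width(b@repeats[[sx]]),
                               mcols(b@repeats[[sx]])$family, sum) / tot
        expect_lt(max(abs(perFam[cfg$repeatConfig$family] -
                          cfg$repeatConfig[[pctCol]]), na.rm = TRUE), 1.5)
    }
})
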