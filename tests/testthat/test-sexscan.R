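# helper: a bare SexDiffTable-shaped GRanges for flag/call tests
fakeSdt <- function(n, covM = 1, covF = 1, hetM = 0.001, hetF = 0.001,
                    chrom = "chr1", width = 1e5) {
    gr <- GRanges(chrom, IRanges(seq(1, by = width, length.out = n),
                                 width = width))
    mcols(gr) <- S4Vectors::DataFrame(
        covM = rep_len(covM, n), covF = rep_len(covF, n),
        covDiffFM = rep_len(covF - covM, n),
        covRatioMF = rep_len(covM / covF, n),
        hetM = rep_len(hetM, n), hetF = rep_len(hetF, n),
        hetDiffMF = rep_len(hetM - hetF, n))
    gr
}

test_that("constant depth yields unit normalized coverage everywhere", {
    sex <- c(a = "M", b = "F")
    cov <- list(
        a = GRanges("chr1", IRanges(seq(1, 1e6, 1000), width = 1000),
                    score = 10),
        b = GRanges("chr1", IRanges(seq(1, 1e6, 1000), width = 1000),
                    score = 25))
    ws <- windowStats(cov, sex, windowSize = 1e5)
    expect_true(all(abs(assay(ws, "coverage") - 1) < 1e-12))
    expect_equal(nrow(ws), 10L)
    expect_error(windowStats(cov["a"], sex, windowSize = 1e5), "b")
})

test_that("window heterozygosity is het calls over callable sites", {
    sex <- c(a = "M", b = "F")
    cov <- list(
        a = GRanges("chr1", IRanges(1, 1000), score = 10),
        b = GRanges("chr1", IRanges(1, 1000), score = 10))
    v <- makeCalls("chr1", c(100L, 200L, 300L), REF = c("A", "A", "A"),
                   ALT = list("T", "T", "T"), QUAL = rep(99, 3),
                   gtA = cbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 0L)),
                   gtB = cbind(a = c(1L, 1L, 0L), b = c(0L, 0L, 0L)),
                   DP = matrix(20L, 3, 2, dimnames = list(NULL, c("a", "b"))),
                   sex = sex)
    ws <- windowStats(cov, sex, variants = v, windowSize = 1000,
                      minCallable = 10)
    expect_equal(unname(assay(ws, "het")[1, "a"]), 2 / 1000)
    expect_equal(unname(assay(ws, "het")[1, "b"]), 0)
    expect_equal(unname(assay(ws, "callable")[1, "a"]), 1000)
})

test_that("outlier flagging hits the nominal rate on homogeneous noise", {
    set.seed(99)
    n <- 1000
    sdt <- fakeSdt(n)
    mcols(sdt)$covDiffFM <- rnorm(n)
    mcols(sdt)$hetDiffMF <- rnorm(n)
    out <- flagOutlierWindows(sdt, ciLevel = 0.95)
    for (col in c("flagCov", "flagHet")) {
        frac <- mean(mcols(out)[[col]] != "none")
        expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.015)
    }
})

test_that("flagging is degenerate-safe and needs enough windows", {
    sdt <- fakeSdt(30)
    w <- testthat::capture_warnings(out <- flagOutlierWindows(sdt))
    expect_length(w, 2L)            # one per constant statistic
    expect_match(w, "constant", all = TRUE)
    expect_true(all(mcols(out)$flagCov == "none"))
    expect_error(flagOutlierWindows(fakeSdt(10)), "20 windows")
})

test_that("swapping sex labels mirrors every flag exactly", {
    set.seed(17)
    n <- 200
    sdt <- fakeSdt(n)
    mcols(sdt)$covDiffFM <- rnorm(n, sd = 0.1)
    mcols(sdt)$hetDiffMF <- rnorm(n, sd = 0.01)
    a <- flagOutlierWindows(sdt)
    swapped <- sdt
    mcols(swapped)$covDiffFM <- -mcols(sdt)$covDiffFM
    mcols(swapped)$hetDiffMF <- -mcols(sdt)$hetDiffMF
    b <- flagOutlierWindows(swapped)
    map <- c(cov_low = "cov_high", cov_high = "cov_low", none = "none")
    expect_equal(unname(map[mcols(a)$flagCov]), mcols(b)$flagCov)
    map2 <- c(het_low = "het_high", het_high = "het_low", none = "none")
    expect_equal(unname(map2[mcols(a)$flagHet]), mcols(b)$flagHet)
})

test_that("region calling applies the classification rules", {
    # five het_high windows at diploid coverage -> one heterogametic region
    sdt <- fakeSdt(30)
    mcols(sdt)$flagCov <- rep("none", 30)
    mcols(sdt)$flagHet <- rep("none", 30)
    mcols(sdt)$flagHet[11:15] <- "het_high"
    mcols(sdt)$hetM[11:15] <- 0.01
    reg <- callRegions(sdt)
    expect_equal(length(reg), 1L)
    expect_equal(mcols(reg)$class, "heterogametic")
    expect_equal(start(reg), start(sdt)[11])
    expect_equal(end(reg), end(sdt)[15])
    expect_equal(mcols(reg)$nWindows, 5L)

    # half coverage with silent male heterozygosity -> homogametic
    sdt2 <- fakeSdt(30, covM = 1, covF = 1)
    mcols(sdt2)$flagCov <- rep("none", 30)
    mcols(sdt2)$flagHet <- rep("none", 30)
    mcols(sdt2)$flagCov[5:9] <- "cov_low"
    mcols(sdt2)$covM[5:9] <- 0.5
    mcols(sdt2)$hetM[5:9] <- 0
    reg2 <- callRegions(sdt2)
    expect_equal(mcols(reg2)$class, "homogametic")
    expect_lt(mcols(reg2)$covRatio, 0.75)

    # conflicting evidence -> homogametic with a warning
    sdt3 <- sdt2
    mcols(sdt3)$hetM[5:9] <- 0.05
    expect_warning(reg3 <- callRegions(sdt3), "conflict")
    expect_equal(mcols(reg3)$class, "homogametic")

    # a run shorter than minRun is not called
    sdt4 <- fakeSdt(30)
    mcols(sdt4)$flagCov <- rep("none", 30)
    mcols(sdt4)$flagHet <- rep("none", 30)
    mcols(sdt4)$flagHet[c(3, 4)] <- "het_high"
    mcols(sdt4)$hetM[c(3, 4)] <- 0.01
    expect_equal(length(callRegions(sdt4)), 0L)

    # gaps up to maxGap are bridged
    sdt5 <- fakeSdt(30)
    mcols(sdt5)$flagCov <- rep("none", 30)
    mcols(sdt5)$flagHet <- rep("none", 30)
    mcols(sdt5)$flagHet[c(10, 11, 13, 14)] <- "het_high"
    mcols(sdt5)$hetM[10:14] <- 0.01
    reg5 <- callRegions(sdt5)
    expect_equal(length(reg5), 1L)
    expect_equal(mcols(reg5)$nWindows, 5L)
})

test_that("region length arithmetic reproduces the published values", {
    f <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t257000000\t304500000\tsex-linked",
                 "chrB\t0\t75000000\tsex-linked"), f)
    regions <- readBed(f)
    expect_equal(regionLengthMb(regions), c(47.5, 75.0))
    expect_equal(regionLengthMb(GRanges("z", IRanges(5, 5))), 1e-6)
})

test_that("the scan recovers simulated sex-linked regions", {
    cfg <- smallConfig(31)
    b <- simulateNeoXY(cfg, components = character())
    ws <- windowStats(b@coverage, b@sex, variants = b@variants,
                      windowSize = 1e5)
    reg <- callRegions(flagOutlierWindows(sexDiffTable(ws)))
    het <- reg[mcols(reg)$class == "heterogametic"]
    hom <- reg[mcols(reg)$class == "homogametic"]
    expect_equal(length(het), 1L)
    expect_lte(abs(start(het) - start(cfg$stratum)), 1e5)
    expect_lte(abs(end(het) - end(cfg$stratum)), 1e5)
    expect_equal(length(hom), 1L)
    expect_lte(abs(end(hom) - end(cfg$xlInterval)), 1e5)
    # the complement is autosomal and tiles the genome
    full <- fillAutosomal(reg, cfg$genome)
    expect_equal(sum(width(full)), sum(cfg$genome))

    # resolution consistency: halving the window moves boundaries <= 1 window
    ws2 <- windowStats(b@coverage, b@sex, variants = b@variants,
                       windowSize = 5e4)
    reg2 <- callRegions(flagOutlierWindows(sexDiffTable(ws2)))
    het2 <- reg2[mcols(reg2)$class == "heterogametic"]
    expect_equal(length(het2), 1L)
    expect_lte(abs(start(het2) - start(het)), 1e5)
    expect_lte(abs(end(het2) - end(het)), 1e5)
})

test_that("the null simulation rarely yields any region call", {
    calls <- vapply(1:30, function(sd) {
        cfg <- smallConfig(4000 + sd, xySnpDivergence = 0, xyIndelRate = 0,
                           pseudogenizationRate = 0)
        cfg$xlInterval <- NULL
        b <- simulateNeoXY(cfg, components = character())
        ws <- windowStats(b@coverage, b@sex, variants = b@variants,
                          windowSize = 1e5)
        reg <- suppressWarnings(
            callRegions(flagOutlierWindows(sexDiffTable(ws))))
        length(reg) > 0
    }, TRUE)
    expect_lte(mean(calls), 0.1 + 3 * sqrt(0.1 * 0.9 / 30))
})
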