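test_that("repeat density merges overlapping hits and respects bounds", {
    sl <- c(chr1 = 2e6)
    hit <- GRanges("chr1", IRanges(1, 5e5))
    d <- repeatDensityWindows(hit, sl, window = 1e6)
    expect_equal(mcols(d)$density, c(50, 0))
    # two identical overlapping hits count once
    d2 <- repeatDensityWindows(c(hit, hit), sl, window = 1e6)
    expect_equal(mcols(d2)$density, mcols(d)$density)
    expect_error(repeatDensityWindows(GRanges("chr1", IRanges(1, 3e6)), sl),
                 "bounds")
    # splitting a hit into adjacent pieces leaves density unchanged
    parts <- GRanges("chr1", IRanges(c(1, 200001), c(200000, 5e5)))
    d3 <- repeatDensityWindows(parts, sl, window = 1e6)
    expect_equal(mcols(d3)$density, mcols(d)$density)
})

test_that("density in simulated data tracks the configured target", {
    cfg <- smallConfig(41)
    b <- simulateNeoXY(cfg, components = "repeats")
    d <- repeatDensityWindows(b@repeats$male, cfg$genome, window = 1e6)
    target <- sum(cfg$repeatConfig$malePct)
    expect_lt(abs(median(mcols(d)$density) - target), 2)
})

test_that("region-vs-genome density comparison behaves at the extremes", {
    sl <- c(chr1 = 3e7)
    set.seed(4)
    hits <- GRanges("chr1", IRanges(sort(sample.int(3e7 - 2000, 3000)),
                                    width = 1000))
    d <- repeatDensityWindows(hits, sl, window = 1e6)
    region <- GRanges("chr1", IRanges(1, 5e6))
    r <- compareRegionDensity(d, region)
    expect_gt(r$p, 0.001)    # no real difference
    # a strong shift is detected
    d2 <- d
    inside <- IRanges::overlapsAny(d2, region)
    mcols(d2)$density[inside] <- mcols(d2)$density[inside] + 10
    r2 <- compareRegionDensity(d2, region)
    expect_lt(r2$p, 0.01)
    expect_equal(r2$medianInside - r$medianInside, 10)
    # all-tied densities give p = 1
    d3 <- d
    mcols(d3)$density <- 5
    expect_equal(compareRegionDensity(d3, region)$p, 1)
    expect_error(compareRegionDensity(d[1:4], GRanges("chr1", IRanges(1, 3e6))),
                 "3 windows")
})

test_that("sex enrichment applies the inclusive 1.1x threshold", {
    tab <- data.frame(family = c("a", "b", "c", "d"),
                      male = c(2.2, 1.0, 0.0, 5.0),
                      female = c(2.0, 1.0, 3.0, 0.0))
    e <- sexEnrichment(tab)
    expect_equal(e$call[e$family == "a"], "male_enriched")   # exactly 1.1
    expect_equal(e$call[e$family == "b"], "none")
    expect_equal(e$call[e$family == "c"], "female_enriched")
    expect_equal(e$call[e$family == "d"], "male_enriched")
    expect_true(is.infinite(e$maleFemaleRatio[e$family == "d"]))
    # sorted by descending max ratio (both one-sided families tie at Inf)
    expect_true(all(c("c", "d") %in% e$family[1:2]))
    expect_warning(sexEnrichment(data.frame(family = "z", male = 0,
                                            female = 0)), "zero")
    # antisymmetry under swapping the sexes
    swapped <- data.frame(family = tab$family, male = tab$female,
                          female = tab$male)
    e2 <- sexEnrichment(swapped)
    map <- c(male_enriched = "female_enriched",
             female_enriched = "male_enriched", none = "none")
    expect_equal(unname(map[e$call[order(e$family)]]),
                 e2$call[order(e2$family)])
})

test_that("divergence landscapes bin abundance by percent divergence", {
    g <- 1e6
    hit <- GRanges("chr1", IRanges(1, 1000))
    mcols(hit)$divergence <- 0.4
    l <- divergenceLandscape(hit, g)
    expect_equal(l$percent[1], 0.1)
    expect_equal(sum(l$percent[-1]), 0)
    # empty input: all-zero histogram
    empty <- GRanges()
    mcols(empty)$divergence <- numeric()
    expect_equal(sum(divergenceLandscape(empty, g)$percent), 0)
    # masses sum to the total repeat percent
    cfg <- smallConfig(43)
    b <- simulateNeoXY(cfg, components = "repeats")
    tot <- sum(cfg$genome)
    l2 <- divergenceLandscape(b@repeats$female, tot)
    expect_equal(sum(l2$percent),
                 100 * sum(width(b@repeats$female)) / tot)
    # the simulated landscape is bimodal: satellite mass near 2-3%,
    # retroelement mass near 15-20%
    expect_gt(sum(l2$percent[l2$binStart %in% 1:4]), 1)
    expect_gt(sum(l2$percent[l2$binStart %in% 14:21]), 5)
    expect_lt(sum(l2$percent[l2$binStart %in% 6:12]), 1)
})
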