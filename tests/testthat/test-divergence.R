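test_that("codon alignment handles identity and single deletions", {
    x <- randomCds(20)
    a <- alignCodons(x, x)
    expect_false(grepl("-", a@x, fixed = TRUE))
    expect_false(grepl("-", a@y, fixed = TRUE))
    expect_equal(length(a@comparable), 19L)   # terminal stop not comparable

    # delete one internal codon from y: exactly one 3-bp gap
    y <- paste0(substr(x, 1, 29), substring(x, 33))
    a2 <- alignCodons(x, y)
    expect_equal(nchar(a2@x), nchar(x))
    gapRuns <- gregexpr("-+", a2@y)[[1]]
    expect_equal(length(gapRuns), 1L)
    expect_equal(attr(gapRuns, "match.length"), 3L)
    expect_error(alignCodons("", x), "empty")
    expect_error(alignCodons("ACGTA", x), "multiple of 3")
})

test_that("codon alignment score equals exhaustive enumeration", {
    set.seed(303)
    for (rep in 1:60) {
        cx <- randomCodon(sample(1:5, 1))
        cy <- randomCodon(sample(1:5, 1))
        a <- alignCodons(paste(cx, collapse = ""), paste(cy, collapse = ""))
        expect_equal(scoreCodonAlignment(a), bruteAlignScore(cx, cy),
                     info = paste(c(cx, "|", cy), collapse = " "))
    }
})

test_that("NG86 counts match the hand-derived single-codon example", {
    # TTT vs TTC: one synonymous difference; 1/3 synonymous site per codon
    a <- codonAlignment("TTT", "TTC")
    r <- ng86(a)
    expect_equal(r@Sd, 1)
    expect_equal(r@Nd, 0)
    expect_equal(r@S, 1 / 3)
    expect_equal(r@N, 8 / 3)
})

test_that("identical sequences give zero distances and a dS_zero flag", {
    x <- randomCds(30)
    r <- ng86(alignCodons(x, x))
    expect_equal(r@Nd, 0)
    expect_equal(r@Sd, 0)
    expect_equal(r@dN, 0)
    expect_equal(r@dS, 0)
    expect_true(is.na(r@omega))
    expect_true("dS_zero" %in% r@flags)
})

test_that("Jukes-Cantor correction matches the closed form", {
    # 10 TTT codons, one mutated to TTC: Sd = 1 over S = 10/3
    x <- paste(rep("TTT", 10), collapse = "")
    y <- paste0("TTC", paste(rep("TTT", 9), collapse = ""))
    r <- ng86(codonAlignment(x, y))
    pS <- 1 / (10 / 3)
    expect_equal(r@pS, pS)
    expect_equal(r@dS, -3 / 4 * log(1 - 4 * pS / 3))
    # pS >= 3/4 leaves the correction undefined
    sat <- ng86(codonAlignment("TTT", "TTC"))   # pS = 3 on one codon
    expect_true(is.na(sat@dS))
    expect_true("jc_undefined" %in% sat@flags)
})

test_that("NG86 path counts equal exhaustive enumeration on random pairs", {
    set.seed(71)
    for (rep in 1:150) {
        c1 <- randomCodon(); c2 <- randomCodon()
        a <- codonAlignment(c1, c2)
        expected <- brutePathCounts(c1, c2)
        if (is.null(expected)) {
            r <- ng86(a)
            expect_true("path_skipped" %in% r@flags)
        } else {
            r <- ng86(a)
            expect_equal(c(r@Sd, r@Nd), unname(expected),
                         info = paste(c1, c2))
            expect_equal(r@S, (bruteSynSites(c1) + bruteSynSites(c2)) / 2)
        }
    }
})

test_that("NG86 is symmetric and additive over concatenation", {
    set.seed(5150)
    x1 <- randomCds(25); x2 <- randomCds(40)
    y1 <- evolveSynonymous(x1, 4)
    y2 <- evolveSynonymous(x2, 6)
    r12 <- ng86(codonAlignment(paste0(x1, x2), paste0(y1, y2)))
    r1 <- ng86(codonAlignment(x1, y1))
    r2 <- ng86(codonAlignment(x2, y2))
    expect_equal(r12@S, r1@S + r2@S)
    expect_equal(r12@N, r1@N + r2@N)
    expect_equal(r12@Sd, r1@Sd + r2@Sd)
    expect_equal(r12@Nd, r1@Nd + r2@Nd)
    sw <- ng86(codonAlignment(y1, x1))
    expect_equal(sw@Sd, r1@Sd)
    expect_equal(sw@Nd, r1@Nd)
    expect_equal(sw@dS, r1@dS)
    expect_equal(sw@dN, r1@dN)
})

test_that("the saturation filter applies the dS and omega thresholds", {
    tab <- data.frame(gene = paste0("g", 1:5),
                      assignment = "sex-linked",
                      dS = c(2.5, 1.0, 0.5, 0, 1.2),
                      omega = c(0.5, 10.5, 1.0, NA, 2),
                      flags = c("dS_saturated", "omega_saturated", "ok",
                                "dS_zero", "jc_undefined"),
                      stringsAsFactors = FALSE)
    kept <- filterPairs(tab)
    expect_setequal(kept$gene, c("g3", "g4"))
    expect_equal(kept$omegaUsable, c(TRUE, FALSE))
})

test_that("Welch summaries match hand calculation and degenerate cases", {
    tab <- data.frame(gene = paste0("g", 1:6),
                      assignment = rep(c("A", "B"), each = 3),
                      dS = c(1, 2, 3, 2, 3, 4),
                      omega = c(1, 1, 1, 1, 1, 1),
                      omegaUsable = TRUE, stringsAsFactors = FALSE)
    s <- summarizeRegions(tab)
    expect_equal(s$medians$medianDs, c(2, 3))
    expect_equal(unname(s$tests$dS$statistic), -sqrt(3 / 2),
                 tolerance = 1e-8)
    expect_equal(unname(s$tests$dS$parameter), 4, tolerance = 1e-8)
    # identical groups: t = 0, p = 1 (omega here)
    expect_equal(unname(s$tests$omega$statistic), 0)
    expect_equal(s$tests$omega$p.value, 1)
    # one region with < 2 pairs: medians only
    tab2 <- tab[c(1, 2, 3, 4), ]
    w <- testthat::capture_warnings(s2 <- summarizeRegions(tab2))
    expect_match(w, "skipped", all = TRUE)   # both the dS and omega tests
    expect_null(s2$tests$dS)
})

test_that("dN/dS recovers simulated synonymous divergence", {
    set.seed(909)
    dTrue <- 0.15
    ests <- replicate(12, {
        x <- randomCds(300)
        S0 <- totalSynSites(substr(x, 1, nchar(x) - 3))
        m <- rpois(1, dTrue * S0)
        y <- paste0(evolveSynonymous(substr(x, 1, nchar(x) - 3), m), "TAA")
        ng86(codonAlignment(x, y))@dS
    })
    se <- sd(ests) / sqrt(length(ests))
    expect_lt(abs(mean(ests) - dTrue), 3 * se + 0.1 * dTrue)
})
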