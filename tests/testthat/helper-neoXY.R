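suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(Biostrings)
})

# ---- small fixture builders ----------------------------------------------

# a compact VariantCalls object from plain vectors
makeCalls <- function(chrom, pos, REF, ALT, QUAL, gtA, gtB, DP,
                      phased = TRUE, sex = NULL, GQ = NULL) {
    gtA <- as.matrix(gtA); gtB <- as.matrix(gtB); DP <- as.matrix(DP)
    ph <- matrix(phased, nrow(gtA), ncol(gtA), dimnames = dimnames(gtA))
    VariantCalls(GRanges(chrom, IRanges(pos, width = nchar(REF))),
                 REF = REF, ALT = as.list(ALT), QUAL = QUAL,
                 alleleA = gtA, alleleB = gtB, phased = ph, DP = DP,
                 GQ = GQ, sex = sex)
}

# a fast small-genome simulation config
smallConfig <- function(seed, ...) {
    defaults <- list(genome = c(neoX = 2e6, chr2 = 1e6),
                     stratum = GRanges("neoX", IRanges(1e6 + 1, 1.5e6)),
                     xlInterval = GRanges("neoX", IRanges(1, 4e5)),
                     nGenesStratum = 8L, nGenesPar = 4L)
    override <- list(...)
    defaults[names(override)] <- override
    do.call(simConfig, c(list(seed = seed), defaults))
}

# random stop-free in-frame CDS ending in TAA
randomCds <- function(nCodons) {
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA"))
    paste0("ATG", paste(sample(sense, nCodons - 2L, replace = TRUE),
                        collapse = ""), "TAA")
}

# ---- independent oracles --------------------------------------------------

aaTable <- Biostrings::GENETIC_CODE

# exhaustive enumeration of all codon-unit global alignments (<= ~6 codons)
bruteAlignScore <- function(cx, cy, match = 2, mismatch = -1, gap = -4) {
    ax <- unname(aaTable[cx]); ay <- unname(aaTable[cy])
    rec <- function(i, j) {
        if (i > length(cx) && j > length(cy)) return(0)
        best <- -Inf
        if (i <= length(cx) && j <= length(cy))
            best <- max(best, rec(i + 1, j + 1) +
                        if (ax[i] == ay[j]) match else mismatch)
        if (i <= length(cx)) best <- max(best, rec(i + 1, j) + gap)
        if (j <= length(cy)) best <- max(best, rec(i, j + 1) + gap)
        best
    }
    rec(1, 1)
}

# score an aligned codon pair of strings under the same scheme
scoreCodonAlignment <- function(aln, match = 2, mismatch = -1, gap = -4) {
    cx <- substring(aln@x, seq(1, nchar(aln@x), 3), seq(3, nchar(aln@x), 3))
    cy <- substring(aln@y, seq(1, nchar(aln@y), 3), seq(3, nchar(aln@y), 3))
    s <- 0
    for (k in seq_along(cx)) {
        if (cx[k] == "---" || cy[k] == "---") s <- s + gap
        else s <- s + if (aaTable[cx[k]] == aaTable[cy[k]]) match else mismatch
    }
    s
}

# independent synonymous-site count of a codon
bruteSynSites <- function(codon) {
    bases <- c("A", "C", "G", "T")
    syn <- 0L
    for (p in 1:3) for (b in bases) {
        if (b == substr(codon, p, p)) next
        nb <- codon
        substr(nb, p, p) <- b
        if (aaTable[nb] == aaTable[codon]) syn <- syn + 1L
    }
    syn / 3
}

# independent path enumeration for the difference counts of one codon pair;
# returns c(sd, nd) averaged over stop-free orderings, or NULL
brutePathCounts <- function(c1, c2) {
    stops <- c("TAA", "TAG", "TGA")
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dp)) return(c(0, 0))
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
        out
    }
    acc <- NULL
    for (ord in perms(dp)) {
        cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
        for (p in ord) {
            nxt <- cur
            substr(nxt, p, p) <- substr(c2, p, p)
            if (nxt %in% stops && nxt != c2) { ok <- FALSE; break }
            if (aaTable[nxt] == aaTable[cur]) sd <- sd + 1 else nd <- nd + 1
            cur <- nxt
        }
        if (ok) acc <- rbind(acc, c(sd, nd))
    }
    if (is.null(acc)) return(NULL)
    colMeans(acc)
}

# random sense codon
randomCodon <- function(n = 1) {
    sense <- setdiff(names(aaTable), c("TAA", "TAG", "TGA"))
    sample(sense, n, replace = TRUE)
}

# evolve a CDS by `m` synonymous single-nucleotide changes drawn uniformly
# from the current sequence's synonymous opportunities
evolveSynonymous <- function(cds, m) {
    for (k in seq_len(m)) {
        cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
        opps <- list()
        for (ci in seq_along(cod)) {
            for (p in 1:3) for (b in c("A", "C", "G", "T")) {
                if (b == substr(cod[ci], p, p)) next
                nb <- cod[ci]
                substr(nb, p, p) <- b
                if (aaTable[nb] == aaTable[cod[ci]])
                    opps[[length(opps) + 1]] <- c(ci, p, b)
            }
        }
        pick <- opps[[sample.int(length(opps), 1)]]
        ci <- as.integer(pick[1]); p <- as.integer(pick[2])
        nb <- cod[ci]; substr(nb, p, p) <- pick[3]
        cod[ci] <- nb
        cds <- paste(cod, collapse = "")
    }
    cds
}

# total synonymous sites of a CDS (pairwise with itself)
totalSynSites <- function(cds) {
    cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    sum(vapply(cod, bruteSynSites, 0))
}

# the crafted 12-record cascade: every rule is exercised once and the mean
# depth over rule-1..3 survivors is exactly 21
craftedCascade12 <- function() {
    samples <- c(s1 = "M", s2 = "F")
    dpOf <- function(d1, d2) c(s1 = d1, s2 = d2)
    pos <- seq(1000L, by = 1000L, length.out = 12L)
    gtA <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 0L), c(1L, 0L),
                 c(0L, 0L), c(0L, 0L), c(0L, 0L), c(0L, 0L),
                 c(0L, 0L), c(1L, 0L), c(0L, 0L), c(1L, 1L))
    gtB <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 0L), c(1L, 0L),
                 c(1L, 0L), c(1L, 0L), c(1L, 0L), c(0L, 0L),
                 c(1L, 0L), c(1L, 0L), c(0L, 0L), c(1L, 1L))
    DP <- rbind(dpOf(10L, 10L),  # r1: QUAL 25
                dpOf(2L, 2L),    # r2: mean depth 2 < 3
                dpOf(3L, 20L),   # r3: het with DP 3
                dpOf(3L, 20L),   # r4: QUAL 45 hom with DP 3
                dpOf(20L, 20L),  # r5: het, QUAL 39 < 2*21
                dpOf(36L, 20L),  # r6: max depth 36 > 21 + 3*sqrt(21)
                dpOf(20L, 20L),  # r7: inside repeat mask
                dpOf(20L, 20L),  # r8..r12 pass
                dpOf(20L, 20L), dpOf(20L, 20L), dpOf(20L, 20L),
                dpOf(20L, 20L))
    colnames(gtA) <- colnames(gtB) <- names(samples)
    qual <- c(25, 100, 100, 45, 39, 100, 100, 60, 80, 90, 120, 100)
    makeCalls("chr1", pos, REF = rep("A", 12), ALT = rep(list("T"), 12),
              QUAL = qual, gtA = gtA, gtB = gtB, DP = DP, sex = samples)
}

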