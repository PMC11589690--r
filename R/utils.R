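# internal helpers

# stage-local seed so bundle components are reproducible independently
stageSeed <- function(seed, offset) {
    (abs(as.integer(seed)) * 97L + offset) %% 2147480017L
}

randomDnaRaw <- function(n) {
    as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, n, replace = TRUE)]
}

randomDna <- function(n) {
    rawToChar(randomDnaRaw(n))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

isStopCodon <- function(codon) codon %in% STOP_CODONS

# amino acid for a codon via the standard code; "*" for stops, NA if ambiguous
aaOf <- function(codon) {
    aa <- Biostrings::GENETIC_CODE[codon]
    unname(aa)
}

splitCodons <- function(seq) {
    n <- nchar(seq)
    substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# pick an alternative base for `base`, optionally avoiding choices that turn
# `codon` (with the base at `pos`) into a stop codon
pickAltBase <- function(base, codon = NULL, pos = NULL) {
    alts <- setdiff(c("A", "C", "G", "T"), base)
    if (!is.null(codon)) {
        ok <- vapply(alts, function(b) {
            cand <- codon
            substr(cand, pos, pos) <- b
            !isStopCodon(cand)
        }, TRUE)
        if (any(ok)) alts <- alts[ok]
    }
    alts[sample.int(length(alts), 1L)]
}

# vectorized: one random alternative base per element of `bases`
randomAlt <- function(bases) {
    altsOf <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
    if (!length(bases)) return(character())
    pick <- sample.int(3L, length(bases), replace = TRUE)
    vapply(seq_along(bases), function(i) altsOf[[bases[i]]][pick[i]], "")
}
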