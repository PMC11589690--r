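#' Extract gametolog (X/Y) coding-sequence pairs
#'
#' Builds, for each gene, consensus neo-X and neo-Y coding sequences by
#' substituting haploid consensus alleles (including indels) into the
#' reference CDS, and assigns the gene to the sex-linked region or the
#' pseudo-autosomal region (PAR) by its coordinates: sex-linked iff the full
#' CDS span lies inside a heterogametic region; genes straddling a region
#' boundary are conservatively assigned PAR with a warning.  Minus-strand
#' genes are returned in coding orientation.
#'
#' @param haploid list with haploid \code{x} and \code{y}
#'   \linkS4class{VariantCalls}, as from \code{\link{regenotypeHaploid}}.
#' @param reference genome \code{DNAStringSet}.
#' @param genes \code{GRangesList} of CDS parts per gene.
#' @param regions classified regions (\code{GRanges} with a \code{class}
#'   column).
#' @return a \linkS4class{GametologPairSet}.
#' @export
extractGametologPairs <- function(haploid, reference, genes, regions) {
    het <- regions[mcols(regions)$class == "heterogametic"]
    xCons <- consensusAlleles(haploid$x)
    yCons <- consensusAlleles(haploid$y)
    ids <- names(genes)
    spans <- unlist(range(genes), use.names = FALSE)
    inside <- GenomicRanges::countOverlaps(spans, het, type = "within",
                                           ignore.strand = TRUE) > 0
    touches <- IRanges::overlapsAny(spans, het, ignore.strand = TRUE)
    straddle <- touches & !inside
    if (any(straddle))
        warning("gene(s) ", paste(ids[straddle], collapse = ", "),
                " span a region boundary; assigned PAR")
    assign <- ifelse(inside, "sex-linked", "PAR")
    partsList <- as.list(genes)
    xs <- ys <- character(length(ids))
    for (i in seq_along(ids)) {
        parts <- partsList[[i]]
        xs[i] <- buildHaplotypeCds(parts, reference, xCons)
        ys[i] <- buildHaplotypeCds(parts, reference, yCons)
    }
    new("GametologPairSet", geneId = ids,
        xSeq = DNAStringSet(stats::setNames(xs, paste0(ids, "_X"))),
        ySeq = DNAStringSet(stats::setNames(ys, paste0(ids, "_Y"))),
        assignment = assign)
}

# majority consensus allele index per site of a haploid panel; ties go to the
# smaller allele index.  Returns a plain list of per-site vectors.
consensusAlleles <- function(calls) {
    a <- assay(calls, "alleleA")
    maxA <- suppressWarnings(max(a, na.rm = TRUE))
    if (!is.finite(maxA)) maxA <- 0L
    cnt <- vapply(0:maxA, function(k) rowSums(a == k, na.rm = TRUE),
                  numeric(nrow(a)))
    if (nrow(a) == 1L) cnt <- matrix(cnt, nrow = 1L)
    cons <- max.col(cnt, ties.method = "first") - 1L
    cons[rowSums(!is.na(a)) == 0L] <- NA_integer_
    gr <- rowRanges(calls)
    list(chrom = as.character(seqnames(gr)), start = start(gr),
         REF = refAllele(calls), ALT = as.list(altAlleles(calls)),
         allele = as.integer(cons))
}

# substitute consensus alleles into the reference CDS of one gene
buildHaplotypeCds <- function(parts, reference, cons) {
    parts <- parts[order(start(parts))]
    partSeq <- character(length(parts))
    for (k in seq_along(parts)) {
        p <- parts[k]
        chrP <- as.character(seqnames(p))
        s <- as.character(Biostrings::subseq(
            reference[[chrP]], start(p), end(p)))
        hits <- which(cons$chrom == chrP &
                      cons$start >= start(p) &
                      cons$start + nchar(cons$REF) - 1L <= end(p) &
                      !is.na(cons$allele) & cons$allele > 0L)
        if (length(hits)) {
            hits <- hits[order(cons$start[hits], decreasing = TRUE)]
            for (h in hits) {
                rel <- cons$start[h] - start(p) + 1L
                ref <- cons$REF[h]
                alt <- cons$ALT[[h]][cons$allele[h]]
                s <- paste0(substr(s, 1L, rel - 1L), alt,
                            substring(s, rel + nchar(ref)))
            }
        }
        partSeq[k] <- s
    }
    if (as.character(strand(parts)[1L]) == "-") {
        partSeq <- rev(vapply(partSeq, function(z)
            as.character(reverseComplement(DNAString(z))), ""))
    }
    paste(partSeq, collapse = "")
}
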