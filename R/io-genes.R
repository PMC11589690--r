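#' Read protein-coding gene models from GFF3
#'
#' Collects CDS features grouped by gene, ordered 5' to 3' on the coding
#' strand.
#'
#' @param path GFF3 file.
#' @return \code{GRangesList}, one element per gene, of CDS parts with a
#'   \code{phase} metadata column.
#' @export
readGeneModels <- function(path) {
    gff <- rtracklayer::import(path, format = "gff3")
    cds <- gff[gff$type == "CDS"]
    if (!length(cds)) return(GRangesList())
    gene <- if (!is.null(cds$gene_id)) cds$gene_id
        else if (!is.null(cds$Parent) && all(lengths(cds$Parent) > 0))
            sub("\\.t[0-9]+$", "", unlist(cds$Parent))
        else cds$ID
    mcols(cds) <- DataFrame(phase = if (is.null(cds$phase)) 0L else cds$phase)
    grl <- S4Vectors::split(cds, gene)
    # order parts 5'->3' on the coding strand
    GRangesList(lapply(grl, function(g) {
        g[order(start(g), decreasing = as.character(strand(g)[1L]) == "-")]
    }))
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS rows for each element of \code{genes}; extra
#' per-gene metadata (e.g. a truth \code{status}) is written as gene-row
#' attributes.
#'
#' @param genes \code{GRangesList} of CDS parts per gene.
#' @param path output path.
#' @param geneMeta optional \code{DataFrame}/data.frame of per-gene attributes
#'   in the same order as \code{genes}.
#' @export
writeGeneModels <- function(genes, path, geneMeta = NULL) {
    ids <- names(genes)
    rows <- unlist(GRangesList(genes), use.names = FALSE)
    span <- unlist(range(genes), use.names = FALSE)
    attrs <- sprintf("ID=%s", ids)
    if (!is.null(geneMeta))
        for (cn in colnames(geneMeta))
            attrs <- paste0(attrs, ";", cn, "=", as.character(geneMeta[[cn]]))
    geneRows <- paste(as.character(seqnames(span)), "neoXY", "gene",
                      start(span), end(span), ".",
                      as.character(strand(span)), ".", attrs, sep = "\t")
    mrnaRows <- paste(as.character(seqnames(span)), "neoXY", "mRNA",
                      start(span), end(span), ".",
                      as.character(strand(span)), ".",
                      sprintf("ID=%s.t1;Parent=%s", ids, ids), sep = "\t")
    parent <- rep(ids, lengths(genes))
    phase <- unlist(lapply(genes, function(g) {
        p <- mcols(g)$phase
        if (is.null(p)) rep(0L, length(g)) else p
    }), use.names = FALSE)
    cdsRows <- paste(as.character(seqnames(rows)), "neoXY", "CDS",
                     start(rows), end(rows), ".",
                     as.character(strand(rows)), phase,
                     sprintf("ID=%s.cds;Parent=%s.t1;gene_id=%s",
                             parent, parent, parent), sep = "\t")
    writeLines(c("##gff-version 3", geneRows, mrnaRows, cdsRows), path)
    invisible(path)
}

#' Read per-sample coverage tracks from a directory of bedGraph files
#'
#' @param dir directory containing \code{<sample>.bedgraph} files.
#' @param samples sample names; defaults to every \code{.bedgraph} basename.
#' @return named list of \code{GRanges} with a \code{score} column (mean
#'   per-base depth over the interval).
#' @export
readCoverageDir <- function(dir, samples = NULL) {
    files <- list.files(dir, pattern = "\\.bedgraph$", full.names = TRUE)
    nm <- sub("\\.bedgraph$", "", basename(files))
    if (!is.null(samples)) {
        miss <- setdiff(samples, nm)
        if (length(miss))
            stop("no coverage track for sample(s): ",
                 paste(miss, collapse = ", "))
        files <- files[match(samples, nm)]
        nm <- samples
    }
    out <- lapply(files, rtracklayer::import, format = "bedGraph")
    names(out) <- nm
    out
}

#' Write per-sample coverage tracks as bedGraph files
#'
#' @param coverage \code{RangedSummarizedExperiment} with a \code{depth}
#'   assay (tiles x samples), as produced by \code{\link{simulateNeoXY}}.
#' @param dir output directory (created if needed).
#' @export
writeCoverageDir <- function(coverage, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tiles <- rowRanges(coverage)
    d <- assay(coverage, "depth")
    for (s in colnames(coverage)) {
        gr <- tiles
        mcols(gr) <- DataFrame(score = d[, s])
        rtracklayer::export(gr, file.path(dir, paste0(s, ".bedgraph")),
                            format = "bedGraph")
    }
    invisible(dir)
}
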