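#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   rowData colData
#' @importFrom SummarizedExperiment "rowData<-"
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet
#'   writeXStringSet reverseComplement translate GENETIC_CODE
NULL

#' Multi-sample variant calls
#'
#' A \linkS4class{RangedSummarizedExperiment} holding genotype calls for a set
#' of samples at a set of sites.  Assays are integer allele indices
#' \code{alleleA} and \code{alleleB} (0 = reference; \code{NA} = missing;
#' \code{alleleB} all-\code{NA} for haploid panels), a logical \code{phased}
#' assay, read depth \code{DP} and genotype quality \code{GQ}.  Row metadata
#' carries \code{REF}, \code{ALT} (a \code{CharacterList}) and the site
#' \code{QUAL}.  Column data may carry a \code{sex} factor (\code{"M"}/\code{"F"}).
#'
#' @export
setClass("VariantCalls",
    contains = "RangedSummarizedExperiment")

setValidity("VariantCalls", function(object) {
    msg <- NULL
    need <- c("alleleA", "alleleB", "phased", "DP", "GQ")
    if (!all(need %in% names(assays(object))))
        msg <- c(msg, paste("missing assays:",
            paste(setdiff(need, names(assays(object))), collapse = ", ")))
    rd <- rowData(object)
    if (!all(c("REF", "ALT", "QUAL") %in% names(rd)))
        msg <- c(msg, "rowData must contain REF, ALT, QUAL")
    if (is.null(msg)) {
        nalt <- lengths(rd$ALT)
        a <- assay(object, "alleleA")
        b <- assay(object, "alleleB")
        bad <- which(a > nalt | b > nalt)
        if (length(bad))
            msg <- c(msg, "allele index exceeds 1 + number of ALT alleles")
        dp <- assay(object, "DP")
        if (any(dp < 0, na.rm = TRUE))
            msg <- c(msg, "negative DP")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a VariantCalls object
#'
#' @param rowRanges \code{GRanges} of variant anchor positions (1-based, as a
#'   \code{GRanges}; width 1 for SNVs, REF length for deletions).
#' @param REF,ALT reference allele (character) and alternate alleles
#'   (\code{CharacterList} or list of character vectors).
#' @param QUAL numeric site quality (phred-like).
#' @param alleleA,alleleB integer matrices of allele indices (sites x samples);
#'   \code{NA} for missing.  For haploid calls pass \code{alleleB = NULL}.
#' @param phased logical matrix; ignored entries may be \code{NA}.
#' @param DP,GQ integer/numeric matrices of per-genotype depth and quality.
#' @param sex optional named character vector (\code{"M"}/\code{"F"}) per sample.
#' @return a \linkS4class{VariantCalls}.
#' @export
VariantCalls <- function(rowRanges, REF, ALT, QUAL, alleleA, alleleB = NULL,
                         phased = NULL, DP = NULL, GQ = NULL, sex = NULL) {
    alleleA <- as.matrix(alleleA)
    ns <- ncol(alleleA)
    if (is.null(alleleB))
        alleleB <- matrix(NA_integer_, nrow(alleleA), ns,
                          dimnames = dimnames(alleleA))
    if (is.null(phased))
        phased <- matrix(FALSE, nrow(alleleA), ns, dimnames = dimnames(alleleA))
    if (is.null(DP))
        DP <- matrix(NA_integer_, nrow(alleleA), ns, dimnames = dimnames(alleleA))
    if (is.null(GQ))
        GQ <- matrix(NA_real_, nrow(alleleA), ns, dimnames = dimnames(alleleA))
    if (!is(ALT, "CharacterList"))
        ALT <- IRanges::CharacterList(ALT)
    mcols(rowRanges)$REF <- REF
    mcols(rowRanges)$ALT <- ALT
    mcols(rowRanges)$QUAL <- QUAL
    cd <- DataFrame(row.names = colnames(alleleA))
    if (!is.null(sex))
        cd$sex <- unname(sex[colnames(alleleA)])
    se <- SummarizedExperiment(
        assays = list(alleleA = alleleA, alleleB = as.matrix(alleleB),
                      phased = as.matrix(phased), DP = as.matrix(DP),
                      GQ = as.matrix(GQ)),
        rowRanges = rowRanges, colData = cd)
    new("VariantCalls", se)
}

#' @describeIn VariantCalls site quality scores.
#' @param x a \code{VariantCalls}.
#' @export
siteQual <- function(x) rowData(x)$QUAL

#' @describeIn VariantCalls reference alleles.
#' @export
refAllele <- function(x) rowData(x)$REF

#' @describeIn VariantCalls alternate alleles (CharacterList).
#' @export
altAlleles <- function(x) rowData(x)$ALT

#' @describeIn VariantCalls logical matrix: is each genotype heterozygous
#'   (both alleles called and unequal)?
#' @export
isHet <- function(x) {
    a <- assay(x, "alleleA"); b <- assay(x, "alleleB")
    !is.na(a) & !is.na(b) & a != b
}

#' @describeIn VariantCalls sample sexes (named by sample), or NULL if unset.
#' @export
sampleSex <- function(x) {
    s <- colData(x)$sex
    if (is.null(s)) return(NULL)
    stats::setNames(as.character(s), colnames(x))
}

#' Pairwise whole-genome alignment blocks
#'
#' One reference-to-query alignment interval per element, with strand,
#' percent identity and (after \code{\link{classifyBlocks}}) a
#' rearrangement classification.
#'
#' @slot refRanges,queryRanges \code{GRanges} of matched length.
#' @slot strand character, \code{"+"} or \code{"-"} per block.
#' @slot identity numeric percent identity in [0, 100].
#' @slot classification character: syntenic, inversion, translocation,
#'   duplication or unclassified.
#' @export
setClass("AlignmentBlocks", representation(
    refRanges = "GRanges", queryRanges = "GRanges",
    strand = "character", identity = "numeric",
    classification = "character"))

setValidity("AlignmentBlocks", function(object) {
    n <- length(object@refRanges)
    msg <- NULL
    if (length(object@queryRanges) != n || length(object@strand) != n ||
        length(object@identity) != n || length(object@classification) != n)
        msg <- c(msg, "slot lengths differ")
    if (any(object@identity < 0 | object@identity > 100, na.rm = TRUE))
        msg <- c(msg, "identity outside [0,100]")
    if (!all(object@strand %in% c("+", "-")))
        msg <- c(msg, "strand must be '+' or '-'")
    if (n && (any(width(object@refRanges) < 1) ||
              any(width(object@queryRanges) < 1)))
        msg <- c(msg, "zero-length block")
    if (is.null(msg)) TRUE else msg
})

#' Construct AlignmentBlocks
#' @param refRanges,queryRanges \code{GRanges} (1-based closed) per block.
#' @param strand character vector, \code{"+"}/\code{"-"}.
#' @param identity percent identity per block.
#' @param classification optional; defaults to "unclassified".
#' @export
AlignmentBlocks <- function(refRanges, queryRanges, strand, identity,
                            classification = NULL) {
    if (is.null(classification))
        classification <- rep("unclassified", length(refRanges))
    new("AlignmentBlocks", refRanges = refRanges, queryRanges = queryRanges,
        strand = as.character(strand), identity = as.numeric(identity),
        classification = classification)
}

#' @describeIn AlignmentBlocks number of blocks.
#' @param x an \code{AlignmentBlocks}.
#' @export
setMethod("length", "AlignmentBlocks", function(x) length(x@refRanges))

#' @describeIn AlignmentBlocks subset blocks.
#' @param i index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "AlignmentBlocks", function(x, i, j, ..., drop = FALSE) {
    AlignmentBlocks(x@refRanges[i], x@queryRanges[i], x@strand[i],
                    x@identity[i], x@classification[i])
})

#' @describeIn AlignmentBlocks reference-side ranges.
#' @export
refRanges <- function(x) x@refRanges

#' @describeIn AlignmentBlocks query-side ranges.
#' @export
queryRanges <- function(x) x@queryRanges

#' @describeIn AlignmentBlocks percent identity.
#' @export
blockIdentity <- function(x) x@identity

#' @describeIn AlignmentBlocks strand per block.
#' @export
blockStrand <- function(x) x@strand

#' @describeIn AlignmentBlocks classification labels.
#' @export
blockClass <- function(x) x@classification

setMethod("show", "AlignmentBlocks", function(object) {
    cat("AlignmentBlocks with", length(object), "blocks\n")
    if (length(object)) {
        cat("  identity:", paste(range(object@identity), collapse = "-"), "\n")
        cat("  classes: ",
            paste(names(table(object@classification)),
                  table(object@classification), sep = "=", collapse = ", "),
            "\n")
    }
})

#' Phased haplotype matrix for a candidate region
#'
#' Two rows per sample (haplotype 1 and 2); entries are allele indices
#' (0 = reference) with \code{NA} for missing.
#'
#' @slot region the region the sites were taken from.
#' @slot sites \code{GRanges} of the sites (columns).
#' @slot alleles integer matrix, 2*nsample rows, one column per site.
#' @slot sample,hap sample name and haplotype index (1/2) per row.
#' @slot sex per-row sample sex.
#' @export
setClass("HaplotypeMatrix", representation(
    region = "GRanges", sites = "GRanges", alleles = "matrix",
    sample = "character", hap = "integer", sex = "character"))

setValidity("HaplotypeMatrix", function(object) {
    msg <- NULL
    if (nrow(object@alleles) != length(object@sample) ||
        length(object@sample) != length(object@hap) ||
        length(object@sex) != length(object@sample))
        msg <- c(msg, "row annotations out of step with allele matrix")
    if (ncol(object@alleles) != length(object@sites))
        msg <- c(msg, "site annotation out of step with allele matrix")
    tab <- table(object@sample)
    if (length(tab) && any(tab != 2L))
        msg <- c(msg, "each sample must contribute exactly two haplotype rows")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "HaplotypeMatrix", function(object) {
    cat("HaplotypeMatrix:", length(unique(object@sample)), "samples x",
        ncol(object@alleles), "sites\n")
})

#' Result of clustering phased haplotypes in a candidate region
#'
#' @slot region the clustered region.
#' @slot yHaplotype named integer (1/2): for each male, which haplotype row
#'   fell in the putative Y cluster (empty unless status is "assigned").
#' @slot separation mean between-cluster over mean within-cluster pairwise
#'   mismatch fraction (Inf when clusters are internally identical).
#' @slot status "assigned", "ambiguous" or "rejected".
#' @export
setClass("GametologAssignment", representation(
    region = "GRanges", yHaplotype = "integer", separation = "numeric",
    status = "character"))

setValidity("GametologAssignment", function(object) {
    if (!object@status %in% c("assigned", "ambiguous", "rejected"))
        return("status must be assigned/ambiguous/rejected")
    TRUE
})

setMethod("show", "GametologAssignment", function(object) {
    cat("GametologAssignment:", object@status,
        sprintf("(separation %.2f)\n", object@separation))
    if (object@status == "assigned")
        cat("  Y haplotype: ",
            paste(names(object@yHaplotype), object@yHaplotype,
                  sep = ":", collapse = " "), "\n")
})

#' A set of gametolog (X/Y) coding-sequence pairs
#'
#' @slot geneId gene identifiers.
#' @slot xSeq,ySeq \code{DNAStringSet}: consensus neo-X and neo-Y coding
#'   sequences in coding orientation.
#' @slot assignment "sex-linked" or "PAR" per gene.
#' @export
setClass("GametologPairSet", representation(
    geneId = "character", xSeq = "DNAStringSet", ySeq = "DNAStringSet",
    assignment = "character"))

setValidity("GametologPairSet", function(object) {
    n <- length(object@geneId)
    if (length(object@xSeq) != n || length(object@ySeq) != n ||
        length(object@assignment) != n)
        return("slot lengths differ")
    if (n && !all(object@assignment %in% c("sex-linked", "PAR")))
        return("assignment must be 'sex-linked' or 'PAR'")
    TRUE
})

#' @describeIn GametologPairSet number of pairs.
#' @param x a \code{GametologPairSet}.
#' @export
setMethod("length", "GametologPairSet", function(x) length(x@geneId))

#' @describeIn GametologPairSet subset pairs.
#' @param i index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "GametologPairSet", function(x, i, j, ..., drop = FALSE) {
    new("GametologPairSet", geneId = x@geneId[i], xSeq = x@xSeq[i],
        ySeq = x@ySeq[i], assignment = x@assignment[i])
})

setMethod("show", "GametologPairSet", function(object) {
    cat("GametologPairSet with", length(object), "gene pairs (",
        sum(object@assignment == "sex-linked"), "sex-linked,",
        sum(object@assignment == "PAR"), "PAR )\n")
})

#' A codon-granular pairwise alignment
#'
#' @slot x,y aligned sequences of equal length; gaps are "-" and occur in
#'   runs of three (one codon).
#' @slot comparable 1-based codon column indices with no gaps, no ambiguity
#'   codes and neither codon a stop.
#' @export
setClass("CodonAlignment", representation(
    x = "character", y = "character", comparable = "integer"))

setValidity("CodonAlignment", function(object) {
    if (nchar(object@x) != nchar(object@y))
        return("aligned lengths differ")
    if (nchar(object@x) %% 3L != 0L)
        return("aligned length not a multiple of 3")
    TRUE
})

setMethod("show", "CodonAlignment", function(object) {
    cat("CodonAlignment:", nchar(object@x) / 3, "codon columns,",
        length(object@comparable), "comparable\n")
})

#' Nei-Gojobori (1986) pairwise dN/dS result
#'
#' Site and difference counts with Jukes-Cantor corrected distances.
#'
#' @slot N,S fractional nonsynonymous and synonymous site counts.
#' @slot Nd,Sd nonsynonymous and synonymous difference counts.
#' @slot pN,pS proportions of differences per site.
#' @slot dN,dS Jukes-Cantor corrected distances (NA when undefined).
#' @slot omega dN/dS (NA when dS is 0 or undefined).
#' @slot flags subset of ok, dS_saturated, omega_saturated, jc_undefined,
#'   dS_zero, path_skipped.
#' @export
setClass("DnDsResult", representation(
    N = "numeric", S = "numeric", Nd = "numeric", Sd = "numeric",
    pN = "numeric", pS = "numeric", dN = "numeric", dS = "numeric",
    omega = "numeric", flags = "character"))

setMethod("show", "DnDsResult", function(object) {
    cat(sprintf(
        "DnDsResult: N=%.2f S=%.2f Nd=%.2f Sd=%.2f dN=%.4f dS=%.4f omega=%s [%s]\n",
        object@N, object@S, object@Nd, object@Sd,
        ifelse(is.na(object@dN), NA, object@dN),
        ifelse(is.na(object@dS), NA, object@dS),
        ifelse(is.na(object@omega), "NA", sprintf("%.3f", object@omega)),
        paste(object@flags, collapse = ",")))
})

#' A ground-truthed synthetic neo-XY data bundle
#'
#' Everything \code{\link{simulateNeoXY}} generates, with the truth needed to
#' score every downstream stage.
#'
#' @slot reference genome sequence.
#' @slot truthRegions \code{GRanges} with a \code{class} column
#'   (heterogametic stratum, homogametic XL, autosomal remainder).
#' @slot variants phased multi-sample \linkS4class{VariantCalls}; row data
#'   carry \code{yAllele}, the truth allele index on the neo-Y haplotype
#'   (NA outside the stratum).
#' @slot coverage \code{RangedSummarizedExperiment} of mean per-base depth in
#'   fixed tiles (assay \code{depth}), samples in columns.
#' @slot sex named character, "M"/"F" per sample.
#' @slot maleYHap named integer: which emitted haplotype (1/2) is the neo-Y
#'   for each male inside the stratum.
#' @slot genes \code{GRangesList} of CDS parts per gene.
#' @slot geneInfo \code{DataFrame}: gene, stratum membership, truth functional
#'   status, truth X and Y coding sequences.
#' @slot repeats list with elements \code{male} and \code{female}: repeat-hit
#'   \code{GRanges} with family, class and divergence columns.
#' @slot blocks \linkS4class{AlignmentBlocks} between the simulated derived
#'   chromosome and its ancestral counterpart.
#' @slot blockTruth truth rearrangement label per block.
#' @slot blockAlignments list of gapped alignment string pairs (ref, qry)
#'   per block.
#' @slot config the generating configuration.
#' @export
setClass("SimBundle", representation(
    reference = "DNAStringSet", truthRegions = "GRanges",
    variants = "VariantCalls", coverage = "RangedSummarizedExperiment",
    sex = "character", maleYHap = "integer", genes = "GRangesList",
    geneInfo = "DataFrame", repeats = "list", blocks = "AlignmentBlocks",
    blockTruth = "character", blockAlignments = "list", config = "list"))

setMethod("show", "SimBundle", function(object) {
    cat("SimBundle:", length(object@reference), "chromosomes,",
        sum(object@sex == "M"), "males +", sum(object@sex == "F"), "females\n")
    cat("  ", nrow(object@variants), "variant sites,",
        length(object@genes), "genes,", length(object@blocks),
        "alignment blocks\n")
})
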