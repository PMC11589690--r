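#' Detect ORF disruptions in a gene copy relative to its parent CDS
#'
#' Aligns the candidate to the parent CDS (codon-granular when both lengths
#' are multiples of 3, else nucleotide-level global alignment) and records
#' \describe{
#'   \item{frameshift}{each gap run after which the cumulative candidate
#'     gap length, scanned 5' to 3', stops being a multiple of 3 (a later
#'     compensating gap does not cancel the event: the intervening peptide
#'     is already garbled).}
#'   \item{premature_stop}{any stop codon in the candidate's reading frame
#'     (the frame implied by the upstream cumulative gaps) strictly before
#'     the terminal codon; the parent's terminal stop is not a disruption.}
#' }
#'
#' @param candidate candidate (e.g. neo-Y) coding sequence.
#' @param parent parent CDS (in-frame, ending in its stop codon).
#' @return data.frame with columns \code{kind}, \code{position} (0-based, in
#'   the parent CDS frame) and \code{detail} (stop codon, or net gap length
#'   mod 3).  Zero rows when the ORF is intact.
#' @export
detectDisruptions <- function(candidate, parent) {
    candidate <- toupper(as.character(candidate))
    parent <- toupper(as.character(parent))
    if (nchar(candidate) < 3L) stop("candidate shorter than one codon")
    if (nchar(candidate) == nchar(parent) && nchar(parent) %% 3L == 0L) {
        aln <- alignCodons(parent, candidate)
        ap <- aln@x; ac <- aln@y
    } else {
        sm <- Biostrings::nucleotideSubstitutionMatrix(2, -1, baseOnly = TRUE)
        pa <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(parent), Biostrings::DNAString(candidate),
            type = "global", substitutionMatrix = sm,
            gapOpening = 4, gapExtension = 1)
        ap <- as.character(Biostrings::alignedPattern(pa))
        ac <- as.character(Biostrings::alignedSubject(pa))
    }
    pv <- strsplit(ap, "")[[1L]]
    cv <- strsplit(ac, "")[[1L]]
    pGap <- pv == "-"; cGap <- cv == "-"
    parentPos <- cumsum(!pGap)          # parent bases consumed through col
    candPos <- cumsum(!cGap)
    shift <- cumsum(as.integer(pGap)) - cumsum(as.integer(cGap))
    out <- data.frame(kind = character(), position = integer(),
                      detail = character(), stringsAsFactors = FALSE)
    # frameshifts: per maximal gap run, compare frame state before and after
    gapCol <- pGap | cGap
    if (any(gapCol)) {
        r <- rle(gapCol)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
            pre <- if (starts[k] == 1L) 0L else shift[starts[k] - 1L]
            post <- shift[ends[k]]
            if (pre %% 3L == 0L && post %% 3L != 0L) {
                pos0 <- if (starts[k] == 1L) 0L else parentPos[starts[k] - 1L]
                out <- rbind(out, data.frame(
                    kind = "frameshift", position = pos0,
                    detail = as.character(((post - pre) %% 3L)),
                    stringsAsFactors = FALSE))
            }
        }
    }
    # premature stops in the candidate's own reading frame
    cod <- splitCodons(candidate)
    nCod <- length(cod)
    for (ci in seq_len(max(0L, nCod - 1L))) {
        if (isStopCodon(cod[ci])) {
            nt <- 3L * (ci - 1L) + 1L          # candidate offset of the stop
            col <- which(candPos == nt & !cGap)[1L]
            pos0 <- if (is.na(col)) nt - 1L
                else parentPos[col] - 1L
            out <- rbind(out, data.frame(
                kind = "premature_stop", position = as.integer(pos0),
                detail = cod[ci], stringsAsFactors = FALSE))
        }
    }
    # a trailing stop that still maps before the parent's terminal codon is
    # also premature (truncation)
    if (nCod >= 1L && isStopCodon(cod[nCod]) &&
        nchar(candidate) %% 3L == 0L) {
        nt <- 3L * (nCod - 1L) + 1L
        col <- which(candPos == nt & !cGap)[1L]
        if (!is.na(col) && parentPos[col] - 1L < nchar(parent) - 3L) {
            out <- rbind(out, data.frame(
                kind = "premature_stop", position = parentPos[col] - 1L,
                detail = cod[nCod], stringsAsFactors = FALSE))
        }
    }
    out[order(out$position), , drop = FALSE]
}

#' Classify gene copies as functional or nonfunctional
#'
#' A copy is nonfunctional iff \code{\link{detectDisruptions}} finds at
#' least one premature stop or frameshift relative to its parent.
#'
#' @param pairs a \linkS4class{GametologPairSet}; the X sequence is the
#'   parent, the Y sequence the candidate.
#' @return data.frame: gene, status, nPrematureStops, nFrameshifts,
#'   positions (comma-separated, 0-based parent frame).
#' @export
classifyPseudogenes <- function(pairs) {
    n <- length(pairs)
    out <- data.frame(gene = pairs@geneId,
                      status = character(n), nPrematureStops = 0L,
                      nFrameshifts = 0L, positions = "",
                      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        d <- detectDisruptions(as.character(pairs@ySeq[[i]]),
                               as.character(pairs@xSeq[[i]]))
        out$status[i] <- if (nrow(d)) "nonfunctional" else "functional"
        out$nPrematureStops[i] <- sum(d$kind == "premature_stop")
        out$nFrameshifts[i] <- sum(d$kind == "frameshift")
        out$positions[i] <- paste(d$position, collapse = ",")
    }
    out
}

#' Proportion of nonfunctional gene copies
#'
#' @param calls data.frame from \code{\link{classifyPseudogenes}} (or any
#'   with a \code{status} column).
#' @param conf confidence level for the exact binomial interval.
#' @return list: n, nNonfunctional, proportion, confInt.
#' @export
degenerationProportion <- function(calls, conf = 0.95) {
    if (!nrow(calls)) stop("no pseudogene calls")
    k <- sum(calls$status == "nonfunctional")
    n <- nrow(calls)
    bt <- stats::binom.test(k, n, conf.level = conf)
    list(n = n, nNonfunctional = k, proportion = k / n,
         confInt = unname(bt$conf.int))
}
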