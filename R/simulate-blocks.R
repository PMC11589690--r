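#' Simulate a rearranged alignment-block set with known truth
#'
#' Builds an ancestral chromosome, carves it into backbone blocks plus the
#' requested structural events, and emits the derived chromosome's
#' alignment blocks with truth labels: inverted segments keep their place
#' with strand \code{-}; translocated segments move to a random other
#' junction; duplicated segments gain an extra copy at a random junction
#' (the extra copy carries the \code{duplication} truth label, the original
#' stays part of the syntenic backbone).  Per-block gapped sequence pairs
#' carry the configured SNP and indel mutation load.
#'
#' @param blockConfig list; recognized entries (with defaults):
#'   \code{ancestralLength} (3e6), \code{nInversions} (2),
#'   \code{nTranslocations} (3), \code{nDuplications} (1),
#'   \code{eventSizeRange} (c(10e3, 40e3)), \code{backboneSizeRange}
#'   (c(10e3, 80e3)), \code{snpRate} (1e-3), \code{indelRate} (1e-4),
#'   \code{indelSizeRange} (c(1, 10)).
#' @param seed integer seed.
#' @return list: \code{blocks} (an \linkS4class{AlignmentBlocks} with ref =
#'   derived chromosome \code{der1}, query = ancestral \code{anc1}),
#'   \code{truth} (label per block), \code{alignments} (list of gapped
#'   (ref, qry) string pairs), \code{expectedSnps} (analytic expectation).
#' @export
simulateRearrangedBlocks <- function(blockConfig = list(), seed = 1L) {
    cfg <- utils::modifyList(list(
        ancestralLength = 3e6, nInversions = 2L, nTranslocations = 3L,
        nDuplications = 1L, eventSizeRange = c(10e3, 40e3),
        backboneSizeRange = c(10e3, 80e3), snpRate = 1e-3,
        indelRate = 1e-4, indelSizeRange = c(1, 10)), blockConfig)
    set.seed(seed)
    L <- as.integer(cfg$ancestralLength)
    nEv <- cfg$nInversions + cfg$nTranslocations + cfg$nDuplications
    ## place non-overlapping event segments
    evLen <- round(stats::runif(nEv, cfg$eventSizeRange[1L],
                                cfg$eventSizeRange[2L]))
    if (sum(evLen) > 0.6 * L)
        stop("requested events cannot be placed without overlap")
    evStart <- integer(nEv)
    placed <- IRanges()
    for (i in seq_len(max(0L, nEv))) {
        for (try in 1:500) {
            s <- sample.int(L - evLen[i] - 1L, 1L)
            cand <- IRanges(s, s + evLen[i] - 1L)
            if (!length(placed) ||
                !any(IRanges::overlapsAny(cand, placed + 1000L))) break
            if (try == 500L)
                stop("requested events cannot be placed without overlap")
        }
        evStart[i] <- s
        placed <- c(placed, cand)
    }
    evType <- rep(c("inversion", "translocation", "duplication"),
                  c(cfg$nInversions, cfg$nTranslocations, cfg$nDuplications))
    if (nEv) {
        o <- order(evStart)
        evStart <- evStart[o]; evLen <- evLen[o]; evType <- evType[o]
    }
    ## segment the ancestral chromosome: backbone chunks + event segments
    segs <- list()   # each: ancStart, ancEnd, type
    cur <- 1L
    addBackbone <- function(from, to) {
        while (from <= to) {
            w <- min(to - from + 1L,
                     round(stats::runif(1L, cfg$backboneSizeRange[1L],
                                        cfg$backboneSizeRange[2L])))
            segs[[length(segs) + 1L]] <<- list(s = from, e = from + w - 1L,
                                               type = "backbone")
            from <- from + w
        }
    }
    for (i in seq_len(max(0L, nEv))) {
        if (evStart[i] > cur) addBackbone(cur, evStart[i] - 1L)
        segs[[length(segs) + 1L]] <- list(s = evStart[i],
                                          e = evStart[i] + evLen[i] - 1L,
                                          type = evType[i])
        cur <- evStart[i] + evLen[i]
    }
    if (cur <= L) addBackbone(cur, L)
    # merge a trailing sliver into its neighbour
    ns <- length(segs)
    if (ns > 1L) for (i in ns:2) {
        if (segs[[i]]$type == "backbone" &&
            segs[[i]]$e - segs[[i]]$s + 1L < 4000L &&
            segs[[i - 1L]]$type == "backbone") {
            segs[[i - 1L]]$e <- segs[[i]]$e
            segs[[i]] <- NULL
        }
    }
    ## derived order: inversions stay (strand -), translocations move,
    ## duplication copies inserted
    der <- lapply(segs, function(sg)
        list(s = sg$s, e = sg$e, strand = if (sg$type == "inversion") "-"
             else "+",
             label = if (sg$type == "inversion") "inversion" else "syntenic",
             moved = sg$type == "translocation"))
    movers <- which(vapply(der, `[[`, TRUE, "moved"))
    for (m in rev(movers)) {
        sg <- der[[m]]
        sg$label <- "translocation"; sg$moved <- FALSE
        der[[m]] <- NULL
        # reinsert at a junction at least 2 positions away from origin
        repeat {
            at <- sample.int(length(der) + 1L, 1L)
            if (abs(at - m) >= 2L || length(der) < 3L) break
        }
        der <- append(der, list(sg), after = at - 1L)
    }
    # a translocated segment that happens to land where query order is
    # still increasing is indistinguishable from backbone; re-seat any such
    # segment at an order-breaking junction
    for (pass in 1:100) {
        qs <- vapply(der, function(z) as.numeric(z$s), 0)
        lab <- vapply(der, `[[`, "", "label")
        bad <- NA_integer_
        for (i in which(lab == "translocation")) {
            prevQ <- if (i > 1L) qs[i - 1L] else -Inf
            nextQ <- if (i < length(der)) qs[i + 1L] else Inf
            if (prevQ < qs[i] && qs[i] < nextQ) { bad <- i; break }
        }
        if (is.na(bad)) break
        sg <- der[[bad]]
        der[[bad]] <- NULL
        qs2 <- vapply(der, function(z) as.numeric(z$s), 0)
        for (try in 1:200) {
            at <- sample.int(length(der) + 1L, 1L)
            prevQ <- if (at > 1L) qs2[at - 1L] else -Inf
            nextQ <- if (at <= length(der)) qs2[at] else Inf
            if (!(prevQ < sg$s && sg$s < nextQ)) break
        }
        der <- append(der, list(sg), after = at - 1L)
    }
    dups <- which(vapply(segs, function(sg) sg$type == "duplication", TRUE))
    for (d in dups) {
        sg <- segs[[d]]
        copy <- list(s = sg$s, e = sg$e, strand = "+", label = "duplication",
                     moved = FALSE)
        # insert away from the original's current position
        origAt <- which(vapply(der, function(z)
            z$s == sg$s && z$label != "duplication", TRUE))[1L]
        # insert away from the original and at an order-breaking junction (a
        # copy dropped where it would be perfectly collinear is in principle
        # indistinguishable from the syntenic backbone)
        qs <- vapply(der, function(z) as.numeric(z$s), 0)
        for (try in 1:200) {
            at <- sample.int(length(der) + 1L, 1L)
            prevQ <- if (at > 1L) qs[at - 1L] else -Inf
            nextQ <- if (at <= length(der)) qs[at] else Inf
            breaksOrder <- !(prevQ < sg$s && sg$s < nextQ)
            if ((is.na(origAt) || abs(at - origAt) >= 2L) &&
                (breaksOrder || length(der) < 3L)) break
        }
        der <- append(der, list(copy), after = at - 1L)
    }
    ## sequences and mutations
    anc <- randomDna(L)
    nb <- length(der)
    alignments <- vector("list", nb)
    refLen <- integer(nb); identity <- numeric(nb)
    for (i in seq_len(nb)) {
        sg <- der[[i]]
        qseq <- substr(anc, sg$s, sg$e)
        if (sg$strand == "-")
            qseq <- as.character(reverseComplement(DNAString(qseq)))
        mut <- mutatePair(qseq, cfg)
        alignments[[i]] <- list(ref = mut$ref, qry = mut$qry)
        refLen[i] <- nchar(gsub("-", "", mut$ref, fixed = TRUE))
        identity[i] <- mut$identity
    }
    refStart <- cumsum(c(1L, refLen[-nb]))
    blocks <- AlignmentBlocks(
        refRanges = GRanges("der1", IRanges(refStart, width = refLen)),
        queryRanges = GRanges("anc1", IRanges(
            vapply(der, function(z) as.numeric(z$s), 0), vapply(der, function(z) as.numeric(z$e), 0))),
        strand = vapply(der, `[[`, "", "strand"),
        identity = identity)
    list(blocks = blocks,
         truth = vapply(der, `[[`, "", "label"),
         alignments = alignments,
         expectedSnps = cfg$snpRate *
             sum(vapply(der, function(z) as.numeric(z$e - z$s + 1), 0)))
}

# mutate a query block into its derived (reference) counterpart; returns
# gapped alignment strings, derived first
mutatePair <- function(qseq, cfg) {
    len <- nchar(qseq)
    q <- strsplit(qseq, "")[[1L]]
    r <- q
    nSnp <- stats::rbinom(1L, len, cfg$snpRate)
    if (nSnp) {
        at <- sample.int(len, nSnp)
        r[at] <- vapply(q[at], pickAltBase, "")
    }
    nInd <- stats::rbinom(1L, len, cfg$indelRate)
    if (nInd) {
        at <- sort(sample.int(len - 1L, min(nInd, len - 1L)),
                   decreasing = TRUE)
        for (p in at) {
            k <- sample(seq(cfg$indelSizeRange[1L], cfg$indelSizeRange[2L]),
                        1L)
            if (stats::runif(1L) < 0.5) {   # deletion in derived
                r[p:min(p + k - 1L, length(r))] <- "-"
            } else {                         # insertion in derived
                ins <- strsplit(randomDna(k), "")[[1L]]
                r <- append(r, ins, after = p)
                q <- append(q, rep("-", k), after = p)
            }
        }
    }
    ncol <- length(q)
    matches <- sum(q == r & q != "-")
    list(ref = paste(r, collapse = ""), qry = paste(q, collapse = ""),
         identity = 100 * matches / ncol)
}
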