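#' Global codon-granular alignment of a gametolog pair
#'
#' Needleman-Wunsch over codon units: +2 when the two codons encode the same
#' amino acid (stop treated as its own symbol), -1 otherwise, -4 per codon
#' gap.  Traceback ties are broken deterministically (diagonal, then up,
#' then left).  Comparable columns are the gap-free columns with no
#' ambiguity codes where neither codon is a stop.
#'
#' @param x,y nucleotide sequences (character or \code{DNAString}), lengths
#'   multiples of 3 and at least one codon.
#' @param match,mismatch,gap codon-level scores.
#' @return a \linkS4class{CodonAlignment}.
#' @export
alignCodons <- function(x, y, match = 2, mismatch = -1, gap = -4) {
    x <- as.character(x); y <- as.character(y)
    if (!nchar(x) || !nchar(y)) stop("empty sequence")
    if (nchar(x) %% 3L || nchar(y) %% 3L)
        stop("sequence length not a multiple of 3")
    cx <- toupper(splitCodons(x)); cy <- toupper(splitCodons(y))
    n <- length(cx); m <- length(cy)
    ax <- aaOf(cx); ay <- aaOf(cy)
    S <- matrix(0, n + 1L, m + 1L)
    S[, 1L] <- gap * (0:n)
    S[1L, ] <- gap * (0:m)
    P <- matrix(0L, n + 1L, m + 1L)  # 1=diag, 2=up (gap in y), 3=left
    P[, 1L] <- 2L; P[1L, ] <- 3L; P[1L, 1L] <- 0L
    jj <- seq_len(m)
    for (i in seq_len(n)) {
        sub <- ifelse(!is.na(ax[i]) & !is.na(ay) & ax[i] == ay,
                      match, mismatch)
        d <- S[i, jj] + sub
        u <- S[i, jj + 1L] + gap
        M <- pmax(d, u)
        # left chains under a linear gap: S_j = gap*j + cummax(A)_j with
        # A_k = M_k - gap*k (k = 0 seeds the chain from column 1)
        A <- c(S[i + 1L, 1L], M - gap * jj)
        row <- gap * jj + cummax(A)[jj]
        row <- pmax(row, M)
        S[i + 1L, jj + 1L] <- row
        P[i + 1L, jj + 1L] <- ifelse(row == d, 1L, ifelse(row == u, 2L, 3L))
    }
    i <- n + 1L; j <- m + 1L
    outx <- character(); outy <- character()
    while (i > 1L || j > 1L) {
        mv <- P[i, j]
        if (mv == 1L) {
            outx <- c(cx[i - 1L], outx); outy <- c(cy[j - 1L], outy)
            i <- i - 1L; j <- j - 1L
        } else if (mv == 2L) {
            outx <- c(cx[i - 1L], outx); outy <- c("---", outy)
            i <- i - 1L
        } else {
            outx <- c("---", outx); outy <- c(cy[j - 1L], outy)
            j <- j - 1L
        }
    }
    comparable <- which(outx != "---" & outy != "---" &
                        !grepl("[^ACGT]", outx) & !grepl("[^ACGT]", outy) &
                        !isStopCodon(outx) & !isStopCodon(outy))
    new("CodonAlignment", x = paste(outx, collapse = ""),
        y = paste(outy, collapse = ""), comparable = as.integer(comparable))
}

#' Wrap two already-aligned sequences as a codon alignment
#'
#' For sequences of equal length (gaps allowed, in runs of three) that are
#' already aligned codon-to-codon; computes the comparable columns.
#'
#' @param x,y aligned sequences of equal length, a multiple of 3.
#' @return a \linkS4class{CodonAlignment}.
#' @export
codonAlignment <- function(x, y) {
    x <- toupper(as.character(x)); y <- toupper(as.character(y))
    if (nchar(x) != nchar(y)) stop("aligned lengths differ")
    cx <- splitCodons(x); cy <- splitCodons(y)
    comparable <- which(!grepl("-", cx, fixed = TRUE) &
                        !grepl("-", cy, fixed = TRUE) &
                        !grepl("[^ACGT]", cx) & !grepl("[^ACGT]", cy) &
                        !isStopCodon(cx) & !isStopCodon(cy))
    new("CodonAlignment", x = x, y = y, comparable = as.integer(comparable))
}

# fractional synonymous site count of one codon (sum over the three
# positions of synonymous single-nucleotide neighbours / 3), memoized
.synCache <- new.env(parent = emptyenv())
synSitesOfCodon <- function(codon) {
    hit <- get0(codon, envir = .synCache)
    if (!is.null(hit)) return(hit)
    aa <- aaOf(codon)
    s <- 0
    for (p in 1:3) {
        base <- substr(codon, p, p)
        for (b in setdiff(c("A", "C", "G", "T"), base)) {
            nb <- codon
            substr(nb, p, p) <- b
            if (!is.na(aaOf(nb)) && aaOf(nb) == aa) s <- s + 1 / 3
        }
    }
    assign(codon, s, envir = .synCache)
    s
}

# memoized path counts for a codon pair
.pathCache <- new.env(parent = emptyenv())
codonPathCountsMemo <- function(c1, c2) {
    key <- paste0(c1, c2)
    hit <- get0(key, envir = .pathCache)
    if (!is.null(hit)) {
        if (identical(hit, "skip")) return(NULL)
        return(hit)
    }
    val <- codonPathCounts(c1, c2)
    assign(key, if (is.null(val)) "skip" else val, envir = .pathCache)
    val
}

# average synonymous/nonsynonymous step counts over all orderings of the
# minimal mutation paths between two codons, excluding paths through stops.
# Returns c(sd, nd) or NULL when every path hits a stop.
codonPathCounts <- function(c1, c2) {
    diffPos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
    k <- length(diffPos)
    if (k == 0L) return(c(0, 0))
    perms <- if (k == 1L) list(diffPos)
        else if (k == 2L) list(diffPos, rev(diffPos))
        else {
            idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                        c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
            lapply(idx, function(o) diffPos[o])
        }
    sds <- nds <- numeric()
    for (ord in perms) {
        cur <- c1
        sd <- nd <- 0
        ok <- TRUE
        for (p in ord) {
            nxt <- cur
            substr(nxt, p, p) <- substr(c2, p, p)
            if (isStopCodon(nxt) && !identical(nxt, c2)) { ok <- FALSE; break }
            if (aaOf(nxt) == aaOf(cur)) sd <- sd + 1 else nd <- nd + 1
            cur <- nxt
        }
        if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
    }
    if (!length(sds)) return(NULL)
    c(mean(sds), mean(nds))
}

#' Nei-Gojobori (1986) dN/dS with Jukes-Cantor correction
#'
#' Counts fractional synonymous (S) and nonsynonymous (N) sites averaged
#' between the two codons of each comparable column, and synonymous (Sd) /
#' nonsynonymous (Nd) differences averaged over all orderings of the
#' minimal mutation paths (paths through stop codons excluded; a column
#' whose every path hits a stop is skipped and flagged).  Proportions are
#' corrected with the Jukes-Cantor formula
#' \code{d = -3/4 log(1 - 4 p / 3)}, undefined when \code{p >= 3/4}.
#'
#' @param aln a \linkS4class{CodonAlignment} with at least one comparable
#'   column.
#' @return a \linkS4class{DnDsResult}.
#' @export
ng86 <- function(aln) {
    cols <- aln@comparable
    if (!length(cols)) stop("no comparable codon columns")
    cx <- splitCodons(aln@x)[cols]
    cy <- splitCodons(aln@y)[cols]
    N <- S <- Nd <- Sd <- 0
    flags <- character()
    for (i in seq_along(cx)) {
        pc <- codonPathCountsMemo(cx[i], cy[i])
        if (is.null(pc)) {
            flags <- union(flags, "path_skipped")
            next
        }
        si <- (synSitesOfCodon(cx[i]) + synSitesOfCodon(cy[i])) / 2
        S <- S + si
        N <- N + 3 - si
        Sd <- Sd + pc[1L]
        Nd <- Nd + pc[2L]
    }
    pN <- if (N > 0) Nd / N else NA_real_
    pS <- if (S > 0) Sd / S else NA_real_
    jc <- function(p) {
        if (is.na(p)) return(NA_real_)
        if (p >= 3 / 4) return(NA_real_)
        -3 / 4 * log(1 - 4 * p / 3)
    }
    dN <- jc(pN); dS <- jc(pS)
    if ((!is.na(pN) && pN >= 3 / 4) || (!is.na(pS) && pS >= 3 / 4))
        flags <- union(flags, "jc_undefined")
    omega <- NA_real_
    if (!is.na(dS) && dS == 0) {
        flags <- union(flags, "dS_zero")
    } else if (!is.na(dN) && !is.na(dS)) {
        omega <- dN / dS
        if (omega >= 10) flags <- union(flags, "omega_saturated")
    }
    if (!is.na(dS) && dS >= 2) flags <- union(flags, "dS_saturated")
    if (!length(flags)) flags <- "ok"
    new("DnDsResult", N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
        dN = dN, dS = dS, omega = omega, flags = flags)
}

#' Pairwise dN/dS table for a gametolog pair set
#'
#' Aligns each X/Y pair at codon granularity and applies \code{\link{ng86}}.
#' Pairs whose Y sequence is frameshifted (length not a multiple of 3) get
#' \code{NA} estimates with flag \code{frameshifted}.
#'
#' @param pairs a \linkS4class{GametologPairSet}.
#' @return data.frame with one row per gene: gene, assignment, N, S, Nd, Sd,
#'   dN, dS, omega, flags (comma-collapsed).
#' @export
gametologDnDs <- function(pairs) {
    n <- length(pairs)
    out <- data.frame(gene = pairs@geneId, assignment = pairs@assignment,
                      N = NA_real_, S = NA_real_, Nd = NA_real_,
                      Sd = NA_real_, dN = NA_real_, dS = NA_real_,
                      omega = NA_real_, flags = "", stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        xs <- as.character(pairs@xSeq[[i]])
        ys <- as.character(pairs@ySeq[[i]])
        if (nchar(ys) %% 3L || nchar(xs) %% 3L || !nchar(ys)) {
            out$flags[i] <- "frameshifted"
            next
        }
        r <- ng86(alignCodons(xs, ys))
        out[i, c("N", "S", "Nd", "Sd", "dN", "dS", "omega")] <-
            c(r@N, r@S, r@Nd, r@Sd, r@dN, r@dS, r@omega)
        out$flags[i] <- paste(r@flags, collapse = ",")
    }
    out
}

#' Saturation filter for dN/dS results
#'
#' Retains pairs with defined, unsaturated estimates: dS below
#' \code{maxDs}, omega below \code{maxOmega} and no Jukes-Cantor failure.
#' Pairs with dS exactly zero are retained (usable for dS summaries); the
#' \code{omegaUsable} column marks rows whose omega enters omega summaries.
#'
#' @param tab data.frame from \code{\link{gametologDnDs}}.
#' @param maxDs,maxOmega saturation thresholds.
#' @return the retained subset with an added \code{omegaUsable} column.
#' @export
filterPairs <- function(tab, maxDs = 2, maxOmega = 10) {
    bad <- grepl("jc_undefined|frameshifted", tab$flags) | is.na(tab$dS)
    keep <- !bad & tab$dS < maxDs &
        (is.na(tab$omega) | tab$omega < maxOmega)
    out <- tab[keep, , drop = FALSE]
    out$omegaUsable <- !is.na(out$omega)
    out
}

#' Per-region divergence summaries and Welch test
#'
#' Reports the median dS and median omega per region and, when both regions
#' retain at least two pairs, Welch's unequal-variance two-sample t test
#' (Welch-Satterthwaite degrees of freedom, two-sided p) on dS and on omega.
#'
#' @param tab filtered table from \code{\link{filterPairs}}.
#' @param by column defining the two groups (default \code{assignment}).
#' @return list with \code{medians} (data.frame) and \code{tests} (list of
#'   \code{htest} or NULL for dS and omega).
#' @export
summarizeRegions <- function(tab, by = "assignment") {
    grp <- tab[[by]]
    med <- do.call(rbind, lapply(split(tab, grp), function(d) data.frame(
        region = d[[by]][1L], n = nrow(d),
        medianDs = stats::median(d$dS, na.rm = TRUE),
        medianOmega = stats::median(d$omega[d$omegaUsable], na.rm = TRUE),
        stringsAsFactors = FALSE)))
    rownames(med) <- NULL
    tests <- list(dS = NULL, omega = NULL)
    lv <- unique(grp)
    if (length(lv) == 2L) {
        g1 <- tab[grp == lv[1L], ]; g2 <- tab[grp == lv[2L], ]
        welch <- function(a, b) {
            a <- a[is.finite(a)]; b <- b[is.finite(b)]
            if (length(a) < 2L || length(b) < 2L) {
                warning("fewer than 2 retained pairs in a region; test skipped")
                return(NULL)
            }
            if (stats::var(a) == 0 && stats::var(b) == 0) {
                eq <- mean(a) == mean(b)
                return(structure(list(
                    statistic = c(t = if (eq) 0 else
                        sign(mean(a) - mean(b)) * Inf),
                    parameter = c(df = length(a) + length(b) - 2),
                    p.value = if (eq) 1 else 0,
                    method = "Welch Two Sample t-test"), class = "htest"))
            }
            stats::t.test(a, b, var.equal = FALSE)
        }
        tests$dS <- welch(g1$dS, g2$dS)
        tests$omega <- welch(g1$omega[g1$omegaUsable],
                             g2$omega[g2$omegaUsable])
    }
    list(medians = med, tests = tests)
}
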