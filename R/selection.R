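#' Assemble a per-haplotype ancestry probability field
#'
#' Stacks the per-haplotype population posterior tracks of a
#' \linkS4class{PaintingResult} into the n_hap x K x npop array consumed by
#' the LDA/LDAS/AAS statistics.
#'
#' @param painting a \linkS4class{PaintingResult} with stored posteriors.
#' @return numeric array with dimensions (haplotypes, SNPs, populations) and
#'   population names on the third dimension.
#' @export
ancestryField <- function(painting) {
    pp <- popProbs(painting)
    if (!length(pp)) stop("painting was run without stored posteriors")
    npop <- nrow(pp[[1]])
    K <- ncol(pp[[1]])
    n <- length(pp)
    P <- array(0, c(n, K, npop),
               dimnames = list(painting@targetIds, NULL, painting@pops))
    for (i in seq_len(n)) P[i, , ] <- t(pp[[i]])
    P
}

#' Linkage disequilibrium of ancestry between two SNPs
#'
#' With \eqn{d_i} the total-variation distance between haplotype i's
#' ancestry vectors at SNPs j and l, LDA compares the observed mean
#' \eqn{D_{obs} = mean_i d_i} with the exact mean \eqn{D_{null}} of d over
#' all ordered haplotype pairs (i at j, i' at l, i != i') - the expectation
#' of the permutation null, computed exactly as a U-statistic:
#' \eqn{LDA = (D_{null} - D_{obs}) / D_{null}}, and 0 when
#' \eqn{D_{null} = 0}.  Identical painting at the two SNPs gives LDA 1;
#' unrelated painting gives LDA near 0.
#'
#' @param field ancestry array from \code{\link{ancestryField}}.
#' @param j,l SNP indices (1-based, \code{j != l}).
#' @return the LDA value (scalar).
#' @export
ldaPair <- function(field, j, l) {
    n <- dim(field)[1]
    if (n < 2) stop("need at least 2 haplotypes")
    X <- field[, j, , drop = FALSE]
    Y <- field[, l, , drop = FALSE]
    dobsTot <- sum(abs(X - Y))
    crossTot <- 0
    for (a in seq_len(dim(field)[3])) {
        x <- sort(X[, 1, a])
        y <- Y[, 1, a]
        cx <- cumsum(x)
        c <- findInterval(y, x)
        crossTot <- crossTot +
            sum(y * c - ifelse(c > 0, cx[pmax(c, 1)], 0) +
                (cx[n] - ifelse(c > 0, cx[pmax(c, 1)], 0)) - y * (n - c))
    }
    dobs <- 0.5 * dobsTot / n
    dnull <- 0.5 * (crossTot - dobsTot) / (n * (n - 1))
    if (dnull <= 0) 0 else (dnull - dobs) / dnull
}

# integral of the piecewise-linear interpolant (kind "lin"), or of the step
# function taking the max/min of neighbouring nodes (kind "max"/"min"),
# over [a, b]; flat continuation beyond the terminal nodes
.integrateNodes <- function(g, v, a, b, kind = "lin") {
    if (b <= a) return(0)
    brk <- c(a, g[g > a & g < b], b)
    w <- diff(brk)
    if (kind == "lin") {
        vb <- approx(g, v, xout = brk, rule = 2, ties = "ordered")$y
        return(sum(w * (vb[-1] + vb[-length(vb)]) / 2))
    }
    # step function over each inter-node piece: value from the flanking nodes
    mid <- (brk[-1] + brk[-length(brk)]) / 2
    fi <- findInterval(mid, g)
    lo <- ifelse(fi == 0L, 1L, fi)                 # flat beyond terminal nodes
    hi <- ifelse(fi == 0L, 1L, pmin(fi + 1L, length(g)))
    vv <- if (kind == "max") pmax(v[lo], v[hi]) else pmin(v[lo], v[hi])
    sum(w * vv)
}

.ldasOne <- function(g, v, gj, X, L) {
    # Eq-style window integral with reflected boundary handling
    seg <- function(a, b, kind) .integrateNodes(g, v, max(a, 0), min(b, L), kind)
    one <- function(kind) {
        if (gj < X) {
            seg(0, gj + X, kind) + seg(2 * gj, gj + X, kind)
        } else if (gj > L - X) {
            seg(gj - X, L, kind) + seg(gj - X, 2 * gj - L, kind)
        } else {
            seg(gj - X, gj + X, kind)
        }
    }
    est <- one("lin")
    upper <- one("max")
    # lower bound: chromosome ends pinned to zero LDA
    gLow <- c(0, g, L); vLow <- c(0, v, 0)
    segL <- function(a, b) .integrateNodes(gLow, vLow, max(a, 0), min(b, L), "min")
    lower <- if (gj < X) {
        segL(0, gj + X) + segL(2 * gj, gj + X)
    } else if (gj > L - X) {
        segL(gj - X, L) + segL(gj - X, 2 * gj - L)
    } else {
        segL(gj - X, gj + X)
    }
    c(est, lower, upper)
}

#' LDA score: windowed integral of LDA around every SNP
#'
#' For each SNP j, integrates the pairwise LDA between j and its neighbours
#' over a window of \code{X} cM each side of j (with the near-boundary parts
#' reflected back into the chromosome), treating LDA as a piecewise-linear
#' function of genetic distance.  Upper and lower bounds replace the linear
#' interpolant by step functions taking the larger/smaller neighbouring
#' value (the lower bound additionally pins the chromosome ends to zero
#' LDA); their difference is the maximum possible integration error.
#' Low LDAS flags SNPs whose surrounding ancestry haplotypes are unexpectedly
#' short.
#'
#' Quality control: a SNP fails when its normalised error
#' (\code{error / mean(ldas)}) reaches \code{delta}, or when any 0.5cM
#' distance band within 3cM of the SNP contains fewer than \code{theta}
#' SNPs.
#'
#' @param field ancestry array from \code{\link{ancestryField}}.
#' @param map the \linkS4class{GeneticMap}.
#' @param X half-window in cM (default 4).
#' @param delta maximum tolerated normalised LDAS error (default 0.3).
#' @param theta minimum SNP count per 0.5cM band (default 10).
#' @return data.frame, one row per SNP: \code{pos}, \code{cm}, \code{ldas},
#'   \code{lower}, \code{upper}, \code{error}, \code{errorNorm},
#'   \code{densityPass}, \code{qcPass}, \code{p} (one-sided low-LDAS normal
#'   p-value over QC-passing SNPs).
#' @export
ldasTrack <- function(field, map, X = 4, delta = 0.3, theta = 10L) {
    cm <- map@cm
    K <- length(cm)
    L <- map@chromLengthCM
    pairs <- cpp_lda_pairs(field, cm, X)
    # adjacency in both orientations
    adj <- vector("list", K)
    ordj <- split(seq_len(nrow(pairs)), pairs$j)
    ordl <- split(seq_len(nrow(pairs)), pairs$l)
    est <- low <- up <- rep(NA_real_, K)
    for (j in seq_len(K)) {
        r1 <- ordj[[as.character(j)]]
        r2 <- ordl[[as.character(j)]]
        nb <- c(pairs$l[r1], pairs$j[r2])
        lv <- c(pairs$lda[r1], pairs$lda[r2])
        g <- c(cm[nb], cm[j])
        v <- c(lv, 1)                       # LDA of a SNP with itself is 1
        o <- order(g)
        res <- .ldasOne(g[o], v[o], cm[j], X, L)
        est[j] <- res[1]; low[j] <- res[2]; up[j] <- res[3]
    }
    err <- up - low
    errNorm <- err / mean(est, na.rm = TRUE)
    dens <- .densityCounts(cm, theta)
    qc <- errNorm < delta & dens & !is.na(est)
    p <- rep(NA_real_, K)
    if (any(qc)) {
        s <- sd(est[qc])
        if (s == 0) stop("zero variance in qc-passing LDAS")
        p[qc] <- pnorm((est[qc] - mean(est[qc])) / s)
    }
    data.frame(pos = map@positions, cm = cm, ldas = est, lower = low,
               upper = up, error = err, errorNorm = errNorm,
               densityPass = dens, qcPass = qc, p = p)
}

.densityCounts <- function(cm, theta) {
    # TRUE where every (m-0.5, m] cM band around the SNP, m = 0.5..3,
    # contains at least theta SNPs
    scm <- sort(cm)
    nle <- function(x) findInterval(x, scm)                    # #cm <= x
    nlt <- function(x) findInterval(x, scm, left.open = TRUE)  # #cm <  x
    nAbsLe <- function(x) nle(cm + x) - nlt(cm - x)            # #|d| <= x
    ok <- rep(TRUE, length(cm))
    for (m in seq(0.5, 3, by = 0.5))
        ok <- ok & (nAbsLe(m) - nAbsLe(m - 0.5) >= theta)
    ok
}

#' Ancestry anomaly score
#'
#' For each SNP, the squared z-scores of the mean ancestry probabilities
#' against their genome-wide mean and standard deviation, summed over
#' ancestries: \eqn{AAS(j) = \sum_a z_a(j)^2}.  P-values come from a Gamma
#' distribution fitted to the genome-wide AAS values by the method of
#' moments (upper tail).  An ancestry with zero variance across the genome
#' is dropped with a warning.
#'
#' @param field ancestry array from \code{\link{ancestryField}}.
#' @return data.frame per SNP: \code{aas}, \code{p}, plus the per-ancestry
#'   mean tracks as a \code{meanAncestry} attribute.
#' @export
aasTrack <- function(field) {
    if (dim(field)[3] < 2) stop("need at least 2 populations")
    pbar <- apply(field, c(2, 3), mean)         # K x npop
    mu <- colMeans(pbar)
    sg <- apply(pbar, 2, sd)
    drop <- sg == 0
    if (any(drop)) {
        warning("dropping zero-variance ancestries: ",
                paste(colnames(pbar)[drop], collapse = ", "))
        pbar <- pbar[, !drop, drop = FALSE]
        mu <- mu[!drop]; sg <- sg[!drop]
    }
    z <- sweep(sweep(pbar, 2, mu), 2, sg, `/`)
    aas <- rowSums(z^2)
    m <- mean(aas); v <- var(aas)
    shape <- m^2 / v; scale <- v / m
    p <- pgamma(aas, shape = shape, scale = scale, lower.tail = FALSE)
    out <- data.frame(aas = aas, p = p)
    attr(out, "meanAncestry") <- pbar
    attr(out, "gamma") <- c(shape = shape, scale = scale)
    out
}

#' Classify selection signals as shared or cohort-specific
#'
#' A SNP is a candidate when any cohort reaches the discovery threshold.
#' Candidates are \code{"shared"} when every other cohort is significant at
#' the replication threshold, \code{"specific"} when every other cohort is
#' insignificant at the exclusion threshold, and \code{"unlabeled"}
#' otherwise.  Default thresholds follow the LDAS convention
#' (1e-6 / 0.05 / 0.1); for AAS use \code{c(1e-50, 1e-10, 1e-5)}.
#'
#' @param pmat matrix of p-values, SNPs x cohorts (>= 2 cohorts).
#' @param thresholds numeric length 3: discovery, replication, exclusion.
#' @return character vector per SNP: \code{"none"}, \code{"shared"},
#'   \code{"specific"} or \code{"unlabeled"}.
#' @export
classifySignals <- function(pmat, thresholds = c(1e-6, 0.05, 0.1)) {
    if (ncol(pmat) < 2) stop("need at least 2 cohorts")
    t1 <- thresholds[1]; t2 <- thresholds[2]; t3 <- thresholds[3]
    apply(pmat, 1, function(p) {
        if (anyNA(p)) return("none")
        cand <- which(p <= t1)
        if (!length(cand)) return("none")
        best <- cand[which.min(p[cand])]
        others <- p[-best]
        if (all(others <= t2)) "shared"
        else if (all(others > t3)) "specific"
        else "unlabeled"
    })
}
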