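# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive: direct enumeration, textbook dense
# recursions and dynamic programming, kept separate from the package's
# sweep/sparse implementations.

makePanel <- function(A, pops = character(0), pos = NULL, chrom = "1") {
    storage.mode(A) <- "integer"
    K <- ncol(A)
    if (is.null(pos)) pos <- seq(5000L, by = 5000L, length.out = K)
    new("HaplotypePanel", chrom = chrom, positions = as.integer(pos),
        alleles = A, sampleIds = sprintf("s%03d", seq_len(nrow(A) / 2)),
        popLabels = pops)
}

uniformMap <- function(panel, cmPerBP = 1e-6 * 100) {
    pos <- positions(panel)
    new("GeneticMap", chrom = panel@chrom, positions = pos,
        cm = pos * cmPerBP, chromLengthCM = max(pos) * cmPerBP)
}

# panel with shared haplotype stretches so long matches exist
correlatedAlleles <- function(nhap, K, copyProb = 0.5) {
    A <- matrix(rbinom(nhap * K, 1L, 0.5), nhap, K)
    for (i in seq(2, nhap, by = 2)) {
        cp <- sample(K, 1)
        A[i, 1:cp] <- A[i - 1, 1:cp]
    }
    storage.mode(A) <- "integer"
    A
}

# all maximal matches between two haplotypes (1-based inclusive intervals)
bruteMaximalPair <- function(x, y, L = 1) {
    r <- rle(x == y)
    e <- cumsum(r$lengths)
    s <- c(1L, head(e, -1L) + 1L)
    keep <- r$values & r$lengths >= L
    data.frame(s = s[keep], e = e[keep])
}

# exhaustive maximal matches of target haplotypes vs a reference matrix
bruteLongMatches <- function(Aref, Atgt, L) {
    out <- list()
    for (t in seq_len(nrow(Atgt)))
        for (r in seq_len(nrow(Aref))) {
            b <- bruteMaximalPair(Atgt[t, ], Aref[r, ], L)
            if (nrow(b))
                out[[length(out) + 1L]] <-
                    data.frame(targetHap = t, refHap = r, s = b$s, e = b$e)
        }
    do.call(rbind, c(out, list(data.frame(targetHap = integer(0),
                                          refHap = integer(0),
                                          s = integer(0), e = integer(0)))))
}

# set-maximal oracle: maximal matches not strictly contained in another
# maximal match of the same target
bruteSetMaximal <- function(Aref, Atgt, excludeSelf = FALSE) {
    mm <- bruteLongMatches(Aref, Atgt, 1L)
    if (excludeSelf) mm <- mm[mm$targetHap != mm$refHap, , drop = FALSE]
    keep <- logical(nrow(mm))
    for (i in seq_len(nrow(mm))) {
        same <- mm$targetHap == mm$targetHap[i]
        keep[i] <- !any(same & mm$s <= mm$s[i] & mm$e >= mm$e[i] &
                        (mm$s < mm$s[i] | mm$e > mm$e[i]))
    }
    mm[keep, , drop = FALSE]
}

matchKey <- function(df) sprintf("%d|%d|%d|%d", df$targetHap, df$refHap, df$s, df$e)

# dense Li & Stephens with mutation, scaled textbook recursions
denseLS <- function(Xref, y, gaps, lambda, mu = 1e-9) {
    N <- nrow(Xref); K <- ncol(Xref)
    V <- ifelse(t(t(Xref) == y), 1 - mu, mu)
    rho <- exp(-lambda * gaps); rhot <- (1 - rho) / N
    f <- matrix(0, N, K); logF <- numeric(K)
    fs <- V[, 1] / N; logF[1] <- log(sum(fs)); f[, 1] <- fs / sum(fs)
    for (j in 2:K) {
        fs <- V[, j] * (rho[j - 1] * f[, j - 1] + rhot[j - 1])
        logF[j] <- logF[j - 1] + log(sum(fs)); f[, j] <- fs / sum(fs)
    }
    b <- matrix(0, N, K); logBs <- numeric(K)
    b[, K] <- 1 / N; logBs[K] <- log(N)
    for (j in (K - 1):1) {
        vb <- V[, j + 1] * b[, j + 1]
        bs <- rho[j] * vb + rhot[j] * sum(vb)
        logBs[j] <- logBs[j + 1] + log(sum(bs)); b[, j] <- bs / sum(bs)
    }
    logPrD <- logF[K]
    post <- matrix(0, N, K)
    for (j in 1:K) { fb <- f[, j] * b[, j]; post[, j] <- fb / sum(fb) }
    lhat <- 0.5 * vapply(seq_len(N), function(i)
        sum(gaps * (post[i, 1:(K - 1)] + post[i, 2:K])), 0)
    chat <- post[, 1]
    for (j in 1:(K - 1)) {
        cross <- f[, j] * b[, j + 1] * V[, j + 1] * rho[j] *
            exp(logF[j] + logBs[j + 1] - logPrD)
        chat <- chat + post[, j + 1] - cross
    }
    list(post = post, lhat = lhat, chat = chat, logPrD = logPrD)
}

# sparse posterior densified from a sparseFB result
densifyPosterior <- function(fb, N, K) {
    sp <- matrix(0, N, K)
    for (j in seq_len(K)) {
        rng <- (fb$offsets[j] + 1):fb$offsets[j + 1]
        fbv <- fb$fcheck[rng] * fb$bcheck[rng]
        sp[fb$donors[rng], j] <- fbv / sum(fbv)
    }
    sp
}

# minimum interval cover size by dynamic programming (gaps jumped for free)
minCoverDP <- function(s, e, K) {
    covered <- logical(K)
    for (i in seq_along(s)) covered[s[i]:e[i]] <- TRUE
    dp <- rep(Inf, K + 1L); dp[K + 1L] <- 0
    for (k in K:1) {
        if (!covered[k]) { dp[k] <- dp[k + 1L]; next }
        for (i in which(s <= k & e >= k))
            dp[k] <- min(dp[k], 1 + dp[e[i] + 1L])
    }
    dp[1]
}

# naive staged Q-longest selection, mirroring the two-stage contract
qlongestOracleStaged <- function(mt, K, Q, Lmin, L0) {
    len <- mt$e - mt$s + 1L
    covLen <- function(cut) {
        cov <- integer(K)
        for (i in which(len >= cut)) {
            rng <- mt$s[i]:mt$e[i]
            cov[rng] <- cov[rng] + 1L
        }
        cov
    }
    inS <- len >= L0
    r <- which(covLen(L0) < Q)
    Lprev <- L0; Lq <- max(L0 %/% 2L, Lmin)
    while (length(r) && Lq >= Lmin && Lprev > Lmin) {
        for (i in which(!inS & len >= Lq & len < Lprev))
            if (any((mt$s[i]:mt$e[i]) %in% r)) inS[i] <- TRUE
        r <- which(covLen(Lq) < Q)
        Lprev <- Lq
        if (Lq == Lmin) break
        Lq <- max(Lq %/% 2L, Lmin)
    }
    cand <- which(inS)
    ord <- cand[order(-mt$lenCM[cand], -len[cand], mt$refHap[cand], mt$s[cand])]
    cov <- integer(K); kept <- integer(0)
    for (i in ord) {
        rng <- mt$s[i]:mt$e[i]
        if (any(cov[rng] < Q)) {
            kept <- c(kept, i)
            cov[rng] <- cov[rng] + 1L
        }
    }
    sort(kept)
}

# spec-style brute-force greedy oracle over ALL maximal matches >= Lmin
qlongestOracleGreedy <- function(mt, K, Q) {
    len <- mt$e - mt$s + 1L
    ord <- order(-mt$lenCM, -len, mt$refHap, mt$s)
    cov <- integer(K); kept <- integer(0)
    for (i in ord) {
        rng <- mt$s[i]:mt$e[i]
        if (any(cov[rng] < Q)) {
            kept <- c(kept, i)
            cov[rng] <- cov[rng] + 1L
        }
    }
    sort(kept)
}
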