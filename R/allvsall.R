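#' Genome-wide all-vs-all painting scores from set-maximal matches
#'
#' Fast unsupervised painting: every haplotype is described by its
#' set-maximal matches to all other individuals' haplotypes.  A match
#' \eqn{[s, e]} covering SNP k receives the weight
#' \eqn{w_{jk} = (k - s_{jk})(e_{jk} - k)} - linear in the distance from
#' each end and quadratic in the match length at its midpoint - and weights
#' are normalised per SNP to local ancestry scores \eqn{p_{jk}}.  Per-SNP
#' scores are summed over the chromosome and converted to genetic length
#' with the weight \eqn{g/K} (total map length in cM over SNP count), so
#' each haplotype's scores across donors sum to g cM.
#'
#' SNPs where every covering match starts or ends exactly at k fall back to
#' a uniform weight over covering donors; SNPs with no covering match borrow
#' the donors of the nearest covered SNP in cM.  Matches between the two
#' haplotypes of the same individual are excluded.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param map the matching \linkS4class{GeneticMap}.
#' @param perSite logical; additionally return the per-SNP sparse scores
#'   (small panels only).
#' @return list with \code{hapScores} (sparse dgCMatrix, haplotype level,
#'   entries in cM), \code{G} (map length in cM), \code{sampleIds}, and
#'   optionally \code{perSite} (per target haplotype, a list with per-SNP
#'   donor/probability vectors).
#' @export
avaPaintScores <- function(panel, map, perSite = FALSE) {
    M <- nHaps(panel)
    K <- nSNPs(panel)
    gcm <- diff(range(map@cm))
    sm <- cpp_set_maximal_within(t(alleles(panel)))
    owner <- hapOwner(panel)
    keep <- owner[sm$targetHap + 1L] != owner[sm$refHap + 1L]
    sm <- lapply(sm, `[`, keep)
    ii <- jj <- integer(0); xx <- numeric(0)
    site <- if (perSite) vector("list", M) else NULL
    for (t in seq_len(M)) {
        rows <- which(sm$targetHap == t - 1L)
        if (!length(rows)) {
            warning("haplotype ", t, " has no cross-individual matches")
            next
        }
        res <- cpp_ava_scores(sm$refHap[rows], sm$s[rows], sm$e[rows],
                              K, M, map@cm, perSite)
        ii <- c(ii, rep(t, length(res$donor)))
        jj <- c(jj, res$donor)
        xx <- c(xx, res$score * gcm / K)
        if (perSite)
            site[[t]] <- list(donor = res$siteDonor, prob = res$siteProb)
    }
    hapScores <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(M, M))
    out <- list(hapScores = hapScores, G = gcm, sampleIds = sampleIds(panel))
    if (perSite) out$perSite <- site
    out
}

#' Aggregate per-chromosome painting scores into a coancestry matrix
#'
#' Sums haplotype-level genome-wide scores into individual level (the two
#' haplotypes of recipient and donor are summed and averaged respectively so
#' each individual's row totals the genome's genetic length) and adds
#' chromosomes together.
#'
#' @param scoresList list of results of \code{\link{avaPaintScores}}, one
#'   per chromosome, over the same individuals in the same order.
#' @return a \linkS4class{CoancestryMatrix} with \code{G} = summed map
#'   length (cM); each row sums to G (up to haplotypes that had no
#'   matches).
#' @export
aggregateCoancestry <- function(scoresList) {
    ids <- scoresList[[1]]$sampleIds
    for (sc in scoresList)
        if (!identical(sc$sampleIds, ids))
            stop("individual sets differ between chromosomes")
    n <- length(ids)
    A <- NULL
    G <- 0
    for (sc in scoresList) {
        H <- sc$hapScores
        # recipient haplotypes: average the two rows (an individual's
        # painting); donor haplotypes: sum the two columns
        fold <- Matrix::sparseMatrix(i = rep(seq_len(n), each = 2L),
                                     j = seq_len(2L * n), x = 1,
                                     dims = c(n, 2L * n))
        Ai <- (fold %*% H %*% Matrix::t(fold)) / 2
        A <- if (is.null(A)) Ai else A + Ai
        G <- G + sc$G
    }
    A <- methods::as(A, "CsparseMatrix")
    Matrix::diag(A) <- 0
    dimnames(A) <- list(ids, ids)
    new("CoancestryMatrix", A = A, G = G, sampleIds = ids)
}

#' Haplotype components from a coancestry matrix
#'
#' Singular value decomposition of \eqn{\log_{10}(A + 1)}; the haplotype
#' components are the first \code{nComp} columns of \eqn{U\sqrt{D}},
#' haplotype-sharing analogues of principal components.  Signs are fixed so
#' each component's largest-magnitude loading is positive.
#'
#' @param A a \linkS4class{CoancestryMatrix} (or plain non-negative matrix).
#' @param nComp number of components; truncated to the numerical rank (with
#'   a warning) when larger.
#' @return an \linkS4class{HCResult}.
#' @export
haplotypeComponents <- function(A, nComp = 10L) {
    ids <- if (is(A, "CoancestryMatrix")) A@sampleIds else
        (rownames(A) %||% sprintf("ind%d", seq_len(nrow(A))))
    M <- as.matrix(if (is(A, "CoancestryMatrix")) A@A else A)
    if (any(M < 0)) stop("coancestry entries must be non-negative")
    L <- log10(M + 1)
    sv <- svd(L)
    rank <- sum(sv$d > max(dim(L)) * .Machine$double.eps * max(sv$d, 1))
    if (nComp > rank) {
        warning("requested ", nComp, " components but rank is ", rank)
        nComp <- rank
    }
    U <- sv$u[, seq_len(nComp), drop = FALSE]
    for (c in seq_len(nComp)) {
        i <- which.max(abs(U[, c]))
        if (U[i, c] < 0) U[, c] <- -U[, c]
    }
    comp <- sweep(U, 2, sqrt(sv$d[seq_len(nComp)]), `*`)
    rownames(comp) <- ids
    colnames(comp) <- sprintf("HC%d", seq_len(nComp))
    new("HCResult", components = comp,
        singularValues = sv$d[seq_len(nComp)], sampleIds = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
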