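#' Sparse forward-backward painting of one target haplotype
#'
#' Runs the mutation-free (\eqn{\mu \to 0}) Li & Stephens forward-backward
#' over the per-SNP donor sets induced by a match set, in normalised form
#' with log-accumulated normalisers.  Returns the per-SNP normalised forward
#' and backward values (aligned to the CSR donor lists), the population
#' posterior track, and the expected copied chunk lengths and counts per
#' donor.
#'
#' @param matchset a \linkS4class{MatchSet} with full coverage for the
#'   target (run \code{\link{imputeEmptyPositions}} first).
#' @param targetHap target haplotype index within the match set.
#' @param map the \linkS4class{GeneticMap}.
#' @param lambda recombination scaling constant (> 0).
#' @param nDonors donor pool size N (defaults to the match set's panel
#'   size).
#' @param donorPops optional character vector of donor population labels
#'   (length = panel haplotypes) used to aggregate the posterior.
#' @param probs logical; compute the population posterior track.
#' @return list with elements \code{donors}, \code{offsets} (per-SNP CSR
#'   donor sets), \code{fcheck}, \code{bcheck} (normalised forward/backward
#'   aligned to \code{donors}), \code{logFcum}, \code{logBcum},
#'   \code{popProbs} (npop x K or NULL), \code{lhat}, \code{chat},
#'   \code{loglik}.
#' @export
sparseFB <- function(matchset, targetHap, map, lambda,
                     nDonors = matchset@nRefHaps, donorPops = NULL,
                     probs = TRUE) {
    stopifnot(lambda > 0)
    m <- matches(matchset)
    mt <- m[m$targetHap == targetHap, , drop = FALSE]
    if (!nrow(mt)) stop("no matches for target haplotype ", targetHap)
    K <- matchset@K
    if (is.null(donorPops)) donorPops <- rep("all", matchset@nRefHaps)
    pops <- sort(unique(donorPops))
    popIdx <- match(donorPops, pops) - 1L
    csr <- cpp_matches_to_csr(mt$s - 1L, mt$e - 1L, mt$refHap - 1L, K)
    res <- cpp_sparse_paint(csr$donors, csr$offsets, as.integer(nDonors),
                            gapMorgans(map), lambda,
                            popIdx, length(pops), probs)
    pp <- NULL
    if (probs) {
        pp <- res$popprob
        rownames(pp) <- pops
    }
    list(donors = csr$donors + 1L, offsets = csr$offsets,
         fcheck = res$fvals, bcheck = res$bvals,
         logFcum = res$logFcum, logBcum = res$logBcum,
         popProbs = pp, lhat = res$lhat, chat = res$chat,
         loglik = res$loglik)
}

.minCoverSegments <- function(s, e, K) {
    # greedy farthest-reach cover of the covered positions by the intervals;
    # gaps with no interval are jumped (each jump starts a new segment)
    o <- order(s)
    s <- s[o]; e <- e[o]
    n <- length(s)
    nseg <- 0L
    cur <- s[1]
    i <- 1L
    maxEnd <- max(e)
    while (cur <= maxEnd) {
        far <- -1L
        while (i <= n && s[i] <= cur) {
            if (e[i] > far) far <- e[i]
            i <- i + 1L
        }
        # intervals already passed may still reach cur
        if (far < cur) {
            # gap: jump to the next interval start
            if (i > n) break
            cur <- s[i]
            next
        }
        nseg <- nseg + 1L
        cur <- far + 1L
    }
    nseg
}

#' Estimate the recombination scaling constant from match segmentation
#'
#' Viterbi-flavoured estimate: with \eqn{\mu = 0} the most probable copying
#' path stays inside stored matches, so the minimum number of contiguous
#' donor segments needed to tile the chromosome equals the minimum interval
#' cover of the match set.  With \eqn{N_{break} = N_{seg} - 1},
#' \eqn{\lambda^* = N_{break} / \sum_j g_j}, averaged over target
#' haplotypes.  Imputed matches are excluded; a chromosome fully covered by
#' one match yields the floor value \code{1e-6}.
#'
#' @param matchset a \linkS4class{MatchSet}.
#' @param map the \linkS4class{GeneticMap}.
#' @return the estimate \eqn{\lambda^*} (scalar).
#' @export
estimateLambda <- function(matchset, map) {
    G <- totalMorgans(map)
    if (G <= 0) stop("map has zero genetic length")
    m <- matches(matchset)
    m <- m[!m$imputed, , drop = FALSE]
    lams <- vapply(seq_len(matchset@nTargetHaps), function(t) {
        mt <- m[m$targetHap == t, , drop = FALSE]
        if (!nrow(mt)) stop("target haplotype ", t, " has no matches")
        nseg <- .minCoverSegments(mt$s, mt$e, matchset@K)
        (nseg - 1) / G
    }, 0)
    max(mean(lams), 1e-6)
}

.paintPools <- function(panel, mode, leaveOneOut, targetOwner) {
    # per-target-haplotype excluded donor haplotype indices
    nInd <- nSamples(panel)
    owner <- hapOwner(panel)
    pops <- popLabels(panel)
    hapsOf <- function(ind) c(2L * ind - 1L, 2L * ind)
    lowestPerPop <- NULL
    if (!is.null(pops))
        lowestPerPop <- vapply(split(seq_len(nInd), pops), min, 0L)
    nTgt <- length(targetOwner)
    lapply(seq_len(nTgt), function(t) {
        ind <- targetOwner[t]   # NA for external targets
        if (mode == "ava") {
            hapsOf(ind)
        } else if (mode == "rvr") {
            others <- lowestPerPop[names(lowestPerPop) != pops[ind]]
            unlist(lapply(c(ind, unname(others)), hapsOf))
        } else { # tvr
            if (leaveOneOut) unlist(lapply(unname(lowestPerPop), hapsOf))
            else integer(0)
        }
    })
}

#' Paint target haplotypes against a reference panel
#'
#' End-to-end sparse painting: Q-longest match finding, imputation of
#' matchless SNPs, estimation of the recombination scaling constant (unless
#' supplied), sparse forward-backward per target haplotype, and aggregation
#' of donor posteriors into populations.  Three modes:
#' \describe{
#'   \item{\code{"tvr"}}{target-vs-reference: paint \code{target_panel}
#'     against \code{ref_panel}; with \code{leaveOneOut = TRUE} one
#'     individual (the lowest-indexed) is excluded from every reference
#'     population, giving targets paintings exchangeable with
#'     reference-vs-reference paintings.}
#'   \item{\code{"rvr"}}{reference-vs-reference panel painting: each
#'     reference haplotype is painted with its own individual excluded plus
#'     the lowest-indexed individual of every other population.}
#'   \item{\code{"ava"}}{all-vs-all: each haplotype painted against all
#'     individuals but its own.}
#' }
#'
#' @param ref_panel reference \linkS4class{HaplotypePanel}; population
#'   labels are required for \code{"rvr"} and for leave-one-out \code{"tvr"}.
#' @param target_panel target \linkS4class{HaplotypePanel} (ignored for
#'   \code{"rvr"}/\code{"ava"}).
#' @param map the \linkS4class{GeneticMap}.
#' @param mode painting mode, see above.
#' @param Q,Lmin,L0 match selection parameters
#'   (\code{\link{reportQLongestMatches}}).
#' @param lambda recombination scaling constant; \code{NULL} (default)
#'   estimates it from the match segmentation via
#'   \code{\link{estimateLambda}}.
#' @param leaveOneOut logical, see mode \code{"tvr"}.
#' @param probs logical; store per-SNP population posterior tracks (turn off
#'   to save memory when only chunk summaries are needed).
#' @return a \linkS4class{PaintingResult}.
#' @export
paintTargets <- function(ref_panel, target_panel = NULL, map,
                         mode = c("tvr", "rvr", "ava"),
                         Q = 10L, Lmin = 20L, L0 = NULL, lambda = NULL,
                         leaveOneOut = FALSE, probs = TRUE) {
    mode <- match.arg(mode)
    if (mode != "tvr") target_panel <- NULL
    within <- is.null(target_panel)
    pops <- popLabels(ref_panel)
    if (is.null(pops)) {
        if (mode == "rvr" || (mode == "tvr" && leaveOneOut))
            stop("reference population labels required for leave-one-out modes")
        pops <- rep("all", nSamples(ref_panel))
    }
    nref <- nHaps(ref_panel)
    if (within) {
        targetOwner <- hapOwner(ref_panel)
        targetIds <- sprintf("%s.%d", sampleIds(ref_panel)[targetOwner],
                             rep(1:2, nSamples(ref_panel)))
    } else {
        targetOwner <- rep(NA_integer_, nHaps(target_panel))
        targetIds <- sprintf("%s.%d", sampleIds(target_panel)[hapOwner(target_panel)],
                             rep(1:2, nSamples(target_panel)))
    }
    excl <- .paintPools(ref_panel, mode, leaveOneOut, targetOwner)
    # check no population is wiped out
    hapPops <- rep(pops, each = 2L)
    for (t in seq_along(excl)) {
        left <- table(hapPops[setdiff(seq_len(nref), excl[[t]])])
        if (length(left) < length(unique(pops)) || any(left == 0))
            stop("leave-one-out empties a reference population; ",
                 "each population needs at least 2 individuals")
    }
    index <- buildPBWT(ref_panel)
    ms <- reportQLongestMatches(index, target_panel, map, Q = Q, Lmin = Lmin,
                                L0 = L0, excludeDonors = excl)
    ms <- imputeEmptyPositions(ms, map)
    if (is.null(lambda)) lambda <- estimateLambda(ms, map)

    K <- nSNPs(ref_panel)
    gaps <- gapMorgans(map)
    G <- sum(gaps)
    popU <- sort(unique(pops))
    popIdxHap <- match(hapPops, popU)
    nTgt <- length(targetIds)
    m <- matches(ms)
    chunkL <- matrix(0, nTgt, nref)
    chunkC <- matrix(0, nTgt, nref)
    pp <- if (probs) vector("list", nTgt) else list()
    for (t in seq_len(nTgt)) {
        mt <- m[m$targetHap == t, , drop = FALSE]
        pool <- setdiff(seq_len(nref), excl[[t]])
        poolIdx <- match(mt$refHap, pool)
        if (anyNA(poolIdx)) stop("internal error: match outside donor pool")
        csr <- cpp_matches_to_csr(mt$s - 1L, mt$e - 1L, poolIdx - 1L, K)
        res <- cpp_sparse_paint(csr$donors, csr$offsets, length(pool), gaps,
                                lambda, popIdxHap[pool] - 1L, length(popU),
                                probs)
        chunkL[t, pool] <- res$lhat
        chunkC[t, pool] <- res$chat
        if (probs) {
            rownames(res$popprob) <- popU
            pp[[t]] <- res$popprob
        }
    }
    colnames(chunkL) <- colnames(chunkC) <-
        sprintf("%s.%d", sampleIds(ref_panel)[hapOwner(ref_panel)],
                rep(1:2, nSamples(ref_panel)))
    rownames(chunkL) <- rownames(chunkC) <- targetIds
    new("PaintingResult", pops = popU, popProbs = pp,
        chunkLengths = chunkL, chunkCounts = chunkC,
        lambda = lambda, targetIds = targetIds, G = G)
}

#' Aggregate chunk lengths by donor population, per individual
#'
#' Averages the two haplotypes of each target individual and sums donor
#' haplotype chunk lengths within donor populations, giving for each target
#' individual the expected copied length from each reference population (the
#' NNLS response vector b).
#'
#' @param painting a \linkS4class{PaintingResult} painted against a
#'   labelled reference panel.
#' @param ref_panel the reference \linkS4class{HaplotypePanel}.
#' @return matrix (target individuals x donor populations), rows summing to
#'   the total map length G in Morgans.
#' @export
chunkLengthsByPop <- function(painting, ref_panel) {
    pops <- popLabels(ref_panel)
    if (is.null(pops)) stop("reference panel has no population labels")
    hapPops <- rep(pops, each = 2L)
    cl <- chunkLengths(painting)
    agg <- t(rowsum(t(cl), hapPops))        # targets x pops
    nInd <- nrow(agg) / 2L
    out <- (agg[2L * seq_len(nInd) - 1L, , drop = FALSE] +
            agg[2L * seq_len(nInd), , drop = FALSE]) / 2
    rownames(out) <- sub("\\.1$", "", rownames(agg)[2L * seq_len(nInd) - 1L])
    out
}
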