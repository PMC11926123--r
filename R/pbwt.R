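#' Build the positional Burrows-Wheeler transform of a panel
#'
#' Computes, for every SNP column, the haplotype ordering by reversed prefix
#' and the divergence (match start) arrays.  The materialised arrays are
#' mainly useful for inspection and verification; the match queries sweep
#' the panel column by column and do not require them.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @return a \linkS4class{PBWTIndex}.
#' @export
buildPBWT <- function(panel) {
    if (nHaps(panel) < 1 || nSNPs(panel) < 1) stop("empty panel")
    res <- cpp_build_pbwt(t(alleles(panel)))
    new("PBWTIndex", alleles = alleles(panel),
        prefix = res$prefix + 1L, divergence = res$divergence + 1L)
}

.matchLenCM <- function(map, s, e) {
    if (is.null(map)) rep(NA_real_, length(s)) else map@cm[e] - map@cm[s]
}

.newMatchSet <- function(df, nTargetHaps, nRefHaps, K,
                         Q = NA_integer_, Lmin = NA_integer_, L0 = NA_integer_) {
    rownames(df) <- NULL
    new("MatchSet", matches = df, nTargetHaps = as.integer(nTargetHaps),
        nRefHaps = as.integer(nRefHaps), K = as.integer(K),
        Q = as.integer(Q), Lmin = as.integer(Lmin), L0 = as.integer(L0))
}

.isSamePanel <- function(index, target_panel) {
    is.null(target_panel) || identical(index@alleles, alleles(target_panel))
}

#' Report all maximal matches of at least L SNPs
#'
#' Every maximal exact match between target haplotypes and the indexed panel
#' whose SNP length is at least \code{L}.  When the target panel is the
#' indexed panel itself (or \code{NULL}), matches are found all-vs-all
#' within the panel and each unordered pair is reported from both sides.
#'
#' @param index a \linkS4class{PBWTIndex}.
#' @param target_panel a \linkS4class{HaplotypePanel}, or \code{NULL} for
#'   within-panel matching.
#' @param L minimum match length in SNPs (>= 1).
#' @param map optional \linkS4class{GeneticMap} used to fill genetic lengths.
#' @return a \linkS4class{MatchSet}.
#' @export
longMatches <- function(index, target_panel = NULL, L, map = NULL) {
    stopifnot(L >= 1)
    K <- ncol(index@alleles)
    nref <- nrow(index@alleles)
    within <- .isSamePanel(index, target_panel)
    ntgt <- if (within) nref else nHaps(target_panel)
    if (L > K) {
        warning("L exceeds the number of SNPs; no matches possible")
        df <- data.frame(targetHap = integer(0), refHap = integer(0),
                         s = integer(0), e = integer(0), lenSNP = integer(0),
                         lenCM = numeric(0), imputed = logical(0))
        return(.newMatchSet(df, ntgt, nref, K, Lmin = L))
    }
    if (within) {
        raw <- cpp_long_matches(t(index@alleles), nref, L, 1L)
        tgt <- c(raw$hap1, raw$hap2) + 1L
        ref <- c(raw$hap2, raw$hap1) + 1L
        s <- c(raw$s, raw$s) + 1L
        e <- c(raw$e, raw$e) + 1L
    } else {
        X <- cbind(t(index@alleles), t(alleles(target_panel)))
        raw <- cpp_long_matches(X, nref, L, 0L)
        tgt <- raw$hap2 - nref + 1L
        ref <- raw$hap1 + 1L
        s <- raw$s + 1L
        e <- raw$e + 1L
    }
    df <- data.frame(targetHap = tgt, refHap = ref, s = s, e = e,
                     lenSNP = e - s + 1L, lenCM = .matchLenCM(map, s, e),
                     imputed = rep(FALSE, length(tgt)))
    df <- df[order(df$targetHap, df$refHap, df$s), , drop = FALSE]
    .newMatchSet(df, ntgt, nref, K, Lmin = L)
}

.dropContained <- function(df) {
    # keep matches whose interval is not strictly contained in another
    # interval of the same target haplotype
    keep <- logical(nrow(df))
    for (t in unique(df$targetHap)) {
        idx <- which(df$targetHap == t)
        iv <- unique(df[idx, c("s", "e")])
        iv <- iv[order(iv$s, -iv$e), , drop = FALSE]
        maxe <- -1L
        dom <- logical(nrow(iv))
        for (r in seq_len(nrow(iv))) {
            if (iv$e[r] <= maxe) dom[r] <- TRUE else maxe <- iv$e[r]
        }
        good <- iv[!dom, , drop = FALSE]
        keep[idx] <- paste(df$s[idx], df$e[idx]) %in% paste(good$s, good$e)
    }
    df[keep, , drop = FALSE]
}

#' Report set-maximal matches
#'
#' For each target haplotype, the matches that are longest at their locus
#' among all panel haplotypes: maximal matches not strictly contained in a
#' longer maximal match of the same target.  Within-panel all-vs-all
#' matching never pairs a haplotype with itself.
#'
#' @inheritParams longMatches
#' @return a \linkS4class{MatchSet}.
#' @export
setMaximalMatches <- function(index, target_panel = NULL, map = NULL) {
    K <- ncol(index@alleles)
    nref <- nrow(index@alleles)
    if (.isSamePanel(index, target_panel)) {
        raw <- cpp_set_maximal_within(t(index@alleles))
        df <- data.frame(targetHap = raw$targetHap + 1L, refHap = raw$refHap + 1L,
                         s = raw$s + 1L, e = raw$e + 1L)
        ntgt <- nref
    } else {
        ms <- longMatches(index, target_panel, L = 1, map = NULL)
        df <- .dropContained(matches(ms))[, c("targetHap", "refHap", "s", "e")]
        ntgt <- nHaps(target_panel)
    }
    df$lenSNP <- df$e - df$s + 1L
    df$lenCM <- .matchLenCM(map, df$s, df$e)
    df$imputed <- rep(FALSE, nrow(df))
    df <- df[order(df$targetHap, df$refHap, df$s), , drop = FALSE]
    .newMatchSet(df, ntgt, nref, K)
}

#' Default initial search length for the Q-longest match query
#'
#' \code{2^ceiling(log2(K/16))} SNPs, floored at \code{Lmin}: a handful of
#' halving rounds while starting above the longest matches typically seen.
#'
#' @param K number of SNPs.
#' @param Lmin minimum match length in SNPs.
#' @return integer initial length L0.
#' @export
defaultL0 <- function(K, Lmin = 20L) {
    max(as.integer(2^ceiling(log2(max(K / 16, 1)))), as.integer(Lmin))
}

#' Find at least Q longest matches at every SNP
#'
#' Two-stage selection over maximal matches.  Stage 1 collects matches of
#' length at least \code{Lmin} SNPs in halving length bands starting from
#' \code{L0}, keeping a band's match only when it covers a SNP that still
#' has fewer than \code{Q} matches.  Stage 2 sorts the collected candidates
#' by descending genetic length (ties: SNP length, donor index, start) and
#' greedily keeps a match iff it covers a SNP with fewer than \code{Q} kept
#' matches.  SNPs may end with fewer than \code{Q} (or zero) matches; see
#' \code{\link{imputeEmptyPositions}}.
#'
#' @inheritParams longMatches
#' @param map a \linkS4class{GeneticMap} (required: stage 2 ranks by genetic
#'   length).
#' @param Q minimum number of matches aimed for at each SNP.
#' @param Lmin minimum match length in SNPs.
#' @param L0 initial search length; default \code{defaultL0(K, Lmin)}.
#' @param excludeDonors optional list, one integer vector of donor haplotype
#'   indices per target haplotype, removed from that target's candidate
#'   matches before selection (leave-one-out painting pools).
#' @return a \linkS4class{MatchSet} with the selection parameters recorded.
#' @export
reportQLongestMatches <- function(index, target_panel = NULL, map,
                                  Q = 10L, Lmin = 20L, L0 = NULL,
                                  excludeDonors = NULL) {
    stopifnot(Q >= 1, Lmin >= 1)
    K <- ncol(index@alleles)
    if (is.null(L0)) L0 <- defaultL0(K, Lmin)
    if (L0 < Lmin) L0 <- Lmin
    raw <- longMatches(index, target_panel,
                       L = min(Lmin, K), map = map)
    m <- matches(raw)
    sel <- vector("list", raw@nTargetHaps)
    for (t in seq_len(raw@nTargetHaps)) {
        mt <- m[m$targetHap == t, , drop = FALSE]
        if (!is.null(excludeDonors) && length(excludeDonors[[t]]))
            mt <- mt[!(mt$refHap %in% excludeDonors[[t]]), , drop = FALSE]
        if (!nrow(mt)) next
        keep <- cpp_qlongest_select(mt$s - 1L, mt$e - 1L, mt$refHap,
                                    mt$lenCM, K, Q, as.integer(Lmin),
                                    as.integer(L0)) + 1L
        sel[[t]] <- mt[keep, , drop = FALSE]
    }
    df <- do.call(rbind, c(sel, list(m[0, , drop = FALSE])))
    .newMatchSet(df, raw@nTargetHaps, raw@nRefHaps, K,
                 Q = Q, Lmin = Lmin, L0 = L0)
}

#' Impute matches into matchless SNPs
#'
#' Every SNP of a target haplotype with zero match coverage receives copies
#' of the donors of the nearest covered SNP in genetic distance (ties go to
#' the left), stored as single-SNP rows flagged \code{imputed}.  A target
#' haplotype with no matches at all is an error.
#'
#' @param matchset a \linkS4class{MatchSet}.
#' @param map the \linkS4class{GeneticMap}.
#' @return a \linkS4class{MatchSet} in which every SNP of every target has
#'   coverage at least 1.
#' @export
imputeEmptyPositions <- function(matchset, map) {
    m <- matches(matchset)
    K <- matchset@K
    cm <- map@cm
    extra <- list()
    for (t in seq_len(matchset@nTargetHaps)) {
        cov <- matchCoverage(matchset, t)
        empty <- which(cov == 0)
        if (!length(empty)) next
        if (length(empty) == K)
            stop("target haplotype ", t, " has no matches on the chromosome")
        covered <- which(cov > 0)
        mt <- m[m$targetHap == t, , drop = FALSE]
        for (k in empty) {
            dl <- suppressWarnings(min(abs(cm[k] - cm[covered[covered < k]])))
            dr <- suppressWarnings(min(abs(cm[covered[covered > k]] - cm[k])))
            src <- if (dl <= dr) {
                max(covered[covered < k])
            } else {
                min(covered[covered > k])
            }
            donors <- unique(mt$refHap[mt$s <= src & mt$e >= src])
            extra[[length(extra) + 1L]] <- data.frame(
                targetHap = t, refHap = donors, s = k, e = k, lenSNP = 1L,
                lenCM = 0, imputed = TRUE)
        }
    }
    if (!length(extra)) return(matchset)
    df <- rbind(m, do.call(rbind, extra))
    df <- df[order(df$targetHap, df$refHap, df$s), , drop = FALSE]
    .newMatchSet(df, matchset@nTargetHaps, matchset@nRefHaps, K,
                 Q = matchset@Q, Lmin = matchset@Lmin, L0 = matchset@L0)
}
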