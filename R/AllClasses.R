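#' HaplotypePanel: phased biallelic haplotypes with sample metadata
#'
#' A 2N x K binary matrix of phased haplotypes (rows are haplotypes, columns
#' SNPs; 0 = reference allele, 1 = alternate), with physical positions,
#' sample identifiers and optional population labels.  Haplotypes 2i-1 and 2i
#' belong to individual i.
#'
#' @slot chrom chromosome identifier.
#' @slot positions integer vector of physical bp positions, strictly
#'   increasing.
#' @slot alleles integer matrix (2N x K) of 0/1 alleles.
#' @slot sampleIds character vector of N individual identifiers.
#' @slot popLabels character vector of N population labels, or length 0 when
#'   unlabelled.
#' @export
setClass("HaplotypePanel",
    representation(chrom = "character", positions = "integer",
                   alleles = "matrix", sampleIds = "character",
                   popLabels = "character"),
    validity = function(object) {
        msg <- NULL
        K <- length(object@positions)
        if (ncol(object@alleles) != K)
            msg <- c(msg, "ncol(alleles) must equal length(positions)")
        if (K > 1 && any(diff(object@positions) <= 0))
            msg <- c(msg, "positions must be strictly increasing")
        if (nrow(object@alleles) %% 2 != 0)
            msg <- c(msg, "haplotype count must be even")
        if (!all(object@alleles %in% c(0L, 1L)))
            msg <- c(msg, "alleles must be 0/1")
        if (length(object@sampleIds) * 2L != nrow(object@alleles))
            msg <- c(msg, "need exactly two haplotypes per sample")
        if (length(object@popLabels) &&
            length(object@popLabels) != length(object@sampleIds))
            msg <- c(msg, "popLabels must match sampleIds")
        if (is.null(msg)) TRUE else msg
    })

#' GeneticMap: cumulative genetic positions for a panel's SNPs
#'
#' Cumulative genetic distance in centiMorgans per SNP, aligned to a
#' \linkS4class{HaplotypePanel}.  Gaps between adjacent SNPs (in Morgans) and
#' the total map length derive from it.
#'
#' @slot chrom chromosome identifier.
#' @slot positions integer bp positions (same as the panel's).
#' @slot cm numeric cumulative cM, non-decreasing.
#' @slot chromLengthCM total chromosome genetic length L (cM); at least
#'   \code{max(cm)}.
#' @export
setClass("GeneticMap",
    representation(chrom = "character", positions = "integer",
                   cm = "numeric", chromLengthCM = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@cm) != length(object@positions))
            msg <- c(msg, "cm and positions must align")
        if (length(object@cm) > 1 && any(diff(object@cm) < 0))
            msg <- c(msg, "cm must be non-decreasing")
        if (length(object@chromLengthCM) != 1 ||
            object@chromLengthCM < max(0, object@cm))
            msg <- c(msg, "chromLengthCM must be a scalar >= max(cm)")
        if (is.null(msg)) TRUE else msg
    })

#' MatchSet: sparse maximal-match intervals against a donor panel
#'
#' Matches between target haplotypes and reference (donor) haplotypes.  Each
#' row is a maximal exact match: target haplotype, donor haplotype, start and
#' end SNP (1-based, inclusive at both ends), genetic length in cM, and an
#' imputation flag for matches copied into otherwise matchless SNPs.
#'
#' @slot matches data.frame with columns targetHap, refHap, s, e, lenSNP,
#'   lenCM, imputed.
#' @slot nTargetHaps,nRefHaps,K panel dimensions.
#' @slot Q,Lmin,L0 selection parameters used (NA when not applicable).
#' @export
setClass("MatchSet",
    representation(matches = "data.frame", nTargetHaps = "integer",
                   nRefHaps = "integer", K = "integer",
                   Q = "integer", Lmin = "integer", L0 = "integer"),
    validity = function(object) {
        m <- object@matches
        need <- c("targetHap", "refHap", "s", "e", "lenSNP", "lenCM", "imputed")
        msg <- NULL
        if (!all(need %in% names(m)))
            msg <- c(msg, paste("matches must have columns",
                                paste(need, collapse = ", ")))
        else if (nrow(m)) {
            if (any(m$s < 1 | m$e > object@K | m$s > m$e))
                msg <- c(msg, "match intervals must satisfy 1 <= s <= e <= K")
            if (any(m$lenSNP != m$e - m$s + 1))
                msg <- c(msg, "lenSNP must equal e - s + 1")
        }
        if (is.null(msg)) TRUE else msg
    })

#' PBWTIndex: positional prefix and divergence arrays over a panel
#'
#' The positional Burrows-Wheeler transform of a haplotype panel: at every
#' SNP column k (0..K sites processed) the haplotypes sorted by reversed
#' prefix, and for each sorted position the start of the match to the
#' previous haplotype in sorted order.
#'
#' @slot alleles the indexed panel's 2N x K allele matrix.
#' @slot prefix integer matrix (2N x (K+1)); column k+1 holds the sorted
#'   haplotype order after k sites (1-based haplotype indices).
#' @slot divergence integer matrix (2N x (K+1)); entry (i, k+1) is the
#'   1-based start SNP of the match between sorted haplotypes i and i-1, or
#'   k+1 when they do not match at site k.
#' @export
setClass("PBWTIndex",
    representation(alleles = "matrix", prefix = "matrix",
                   divergence = "matrix"),
    validity = function(object) {
        M <- nrow(object@alleles)
        if (nrow(object@prefix) != M || nrow(object@divergence) != M)
            return("prefix/divergence must have one row per haplotype")
        if (!all(apply(object@prefix, 2, function(a) all(sort(a) == seq_len(M)))))
            return("each prefix column must be a permutation of haplotypes")
        TRUE
    })

#' PaintingResult: sparse-HMM painting of target haplotypes
#'
#' Per-target-haplotype population posterior tracks, expected copied chunk
#' lengths and counts per donor haplotype, and the recombination scaling
#' constant used.
#'
#' @slot pops donor population names (posterior rows).
#' @slot popProbs list, one npop x K matrix per target haplotype (may be
#'   empty when probabilities were not requested).
#' @slot chunkLengths matrix (targets x donor haplotypes) of expected copied
#'   length in Morgans; zero columns for donors excluded from a target's
#'   pool.  Rows sum to the total map length G.
#' @slot chunkCounts matrix of expected chunk counts, same shape.
#' @slot lambda recombination scaling constant used for the HMM.
#' @slot targetIds character labels of target haplotypes.
#' @slot G total map length in Morgans.
#' @export
setClass("PaintingResult",
    representation(pops = "character", popProbs = "list",
                   chunkLengths = "matrix", chunkCounts = "matrix",
                   lambda = "numeric", targetIds = "character", G = "numeric"))

#' CoancestryMatrix: genome-wide expected copied chunk lengths
#'
#' Individual-by-individual sparse matrix A of expected copied chunk lengths
#' (centiMorgans) aggregated over chromosomes from all-vs-all set-maximal
#' painting.  The diagonal is zero and every row sums to the total genetic
#' length G.
#'
#' @slot A sparse dgCMatrix, rows = recipients, columns = donors.
#' @slot G total genetic length in cM.
#' @slot sampleIds individual identifiers.
#' @export
setClass("CoancestryMatrix",
    representation(A = "Matrix", G = "numeric", sampleIds = "character"),
    validity = function(object) {
        if (nrow(object@A) != ncol(object@A)) return("A must be square")
        if (length(object@sampleIds) != nrow(object@A))
            return("sampleIds must match A")
        if (any(Matrix::diag(object@A) != 0)) return("diagonal of A must be 0")
        TRUE
    })

#' HCResult: haplotype components from the coancestry matrix
#'
#' The first n columns of \eqn{U \sqrt{D}} from the singular value
#' decomposition of \eqn{\log_{10}(A + 1)}, ordered by descending singular
#' value, with a deterministic sign convention (largest-magnitude loading of
#' each component positive).
#'
#' @slot components N x n matrix of haplotype components.
#' @slot singularValues the corresponding singular values.
#' @slot sampleIds individual identifiers.
#' @export
setClass("HCResult",
    representation(components = "matrix", singularValues = "numeric",
                   sampleIds = "character"))
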