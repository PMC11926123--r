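#' @name panel-accessors
#' @title Accessors for HaplotypePanel and GeneticMap
#'
#' @description \code{nHaps}, \code{nSamples} and \code{nSNPs} return panel
#' dimensions; \code{alleles}, \code{positions}, \code{sampleIds} and
#' \code{popLabels} return slots; \code{hapOwner} maps haplotype index to
#' individual index; \code{gapMorgans} returns the K-1 inter-SNP gaps
#' \eqn{g_j} in Morgans and \code{totalMorgans} their sum G.
#'
#' @param x a \linkS4class{HaplotypePanel} or \linkS4class{GeneticMap}.
#' @return vectors or scalars as described.
NULL

#' @rdname panel-accessors
#' @export
nHaps <- function(x) nrow(x@alleles)

#' @rdname panel-accessors
#' @export
nSamples <- function(x) length(x@sampleIds)

#' @rdname panel-accessors
#' @export
nSNPs <- function(x) {
    if (is(x, "GeneticMap")) length(x@cm) else length(x@positions)
}

#' @rdname panel-accessors
#' @export
alleles <- function(x) x@alleles

#' @rdname panel-accessors
#' @export
positions <- function(x) x@positions

#' @rdname panel-accessors
#' @export
sampleIds <- function(x) x@sampleIds

#' @rdname panel-accessors
#' @export
popLabels <- function(x) {
    if (length(x@popLabels)) x@popLabels else NULL
}

#' @rdname panel-accessors
#' @export
hapOwner <- function(x) rep(seq_len(nSamples(x)), each = 2L)

#' @rdname panel-accessors
#' @export
geneticCM <- function(x) x@cm

#' @rdname panel-accessors
#' @export
gapMorgans <- function(x) diff(x@cm) / 100

#' @rdname panel-accessors
#' @export
totalMorgans <- function(x) sum(gapMorgans(x))

#' @name matchset-accessors
#' @title Accessors for MatchSet
#'
#' @description \code{matches} returns the match table; \code{matchCoverage}
#' the per-SNP number of stored matches covering each SNP for one target
#' haplotype.
#'
#' @param x a \linkS4class{MatchSet}.
#' @param targetHap target haplotype index (1-based).
#' @param imputed logical; include imputed matches in the coverage count.
#' @return \code{matches}: data.frame; \code{matchCoverage}: integer K-vector.
NULL

#' @rdname matchset-accessors
#' @export
matches <- function(x) x@matches

#' @rdname matchset-accessors
#' @export
matchCoverage <- function(x, targetHap, imputed = TRUE) {
    m <- x@matches[x@matches$targetHap == targetHap, , drop = FALSE]
    if (!imputed) m <- m[!m$imputed, , drop = FALSE]
    cov <- integer(x@K)
    if (nrow(m)) {
        d <- integer(x@K + 1L)
        for (i in seq_len(nrow(m))) {
            d[m$s[i]] <- d[m$s[i]] + 1L
            d[m$e[i] + 1L] <- d[m$e[i] + 1L] - 1L
        }
        cov <- cumsum(d[seq_len(x@K)])
    }
    cov
}

#' @name painting-accessors
#' @title Accessors for PaintingResult
#'
#' @description \code{popProbs} returns the per-haplotype population
#' posterior matrices; \code{chunkLengths} and \code{chunkCounts} the donor
#' summaries; \code{paintingDosage} averages the two haplotype tracks of each
#' individual into an npop x K dosage matrix per individual.
#'
#' @param x a \linkS4class{PaintingResult}.
#' @return as described per accessor.
NULL

#' @rdname painting-accessors
#' @export
popProbs <- function(x) x@popProbs

#' @rdname painting-accessors
#' @export
chunkLengths <- function(x) x@chunkLengths

#' @rdname painting-accessors
#' @export
chunkCounts <- function(x) x@chunkCounts

#' @rdname painting-accessors
#' @export
paintingDosage <- function(x) {
    stopifnot(length(x@popProbs) %% 2 == 0, length(x@popProbs) > 0)
    nInd <- length(x@popProbs) / 2L
    lapply(seq_len(nInd), function(i)
        (x@popProbs[[2L * i - 1L]] + x@popProbs[[2L * i]]) / 2)
}

#' @name coancestry-accessors
#' @title Accessors for CoancestryMatrix and HCResult
#' @param x a \linkS4class{CoancestryMatrix} or \linkS4class{HCResult}.
#' @return \code{coancestry}: the sparse matrix A; \code{hapComponents}: the
#'   component matrix; \code{singularValues}: its singular values.
NULL

#' @rdname coancestry-accessors
#' @export
coancestry <- function(x) x@A

#' @rdname coancestry-accessors
#' @export
hapComponents <- function(x) x@components

#' @rdname coancestry-accessors
#' @export
singularValues <- function(x) x@singularValues

setMethod("show", "HaplotypePanel", function(object) {
    cat("HaplotypePanel:", nSamples(object), "individuals (",
        nHaps(object), "haplotypes ) x", nSNPs(object), "SNPs on",
        object@chrom, "\n")
    if (length(object@popLabels))
        cat("  populations:",
            paste(sprintf("%s(%d)", names(table(object@popLabels)),
                          table(object@popLabels)), collapse = " "), "\n")
})

setMethod("show", "GeneticMap", function(object) {
    cat("GeneticMap:", nSNPs(object), "SNPs on", object@chrom,
        sprintf("spanning %.4f cM (G = %.6f Morgans)\n",
                diff(range(object@cm)), totalMorgans(object)))
})

setMethod("show", "MatchSet", function(object) {
    cat("MatchSet:", nrow(object@matches), "matches,",
        object@nTargetHaps, "target haplotypes vs",
        object@nRefHaps, "donor haplotypes,", object@K, "SNPs\n")
    if (!is.na(object@Q))
        cat(sprintf("  Q = %d, Lmin = %d, L0 = %d; %d imputed\n", object@Q,
                    object@Lmin, object@L0, sum(object@matches$imputed)))
})

setMethod("show", "PBWTIndex", function(object) {
    cat("PBWTIndex over", nrow(object@alleles), "haplotypes x",
        ncol(object@alleles), "SNPs\n")
})

setMethod("show", "PaintingResult", function(object) {
    cat("PaintingResult:", length(object@targetIds), "target haplotypes,",
        length(object@pops), "donor populations, lambda =",
        signif(object@lambda, 6), "\n")
    cat(sprintf("  G = %.6f Morgans; posteriors %s\n", object@G,
                if (length(object@popProbs)) "stored" else "not stored"))
})

setMethod("show", "CoancestryMatrix", function(object) {
    cat("CoancestryMatrix:", nrow(object@A), "x", ncol(object@A),
        sprintf("individuals, G = %.4f cM, density %.3f\n", object@G,
                Matrix::nnzero(object@A) / length(object@A)))
})

setMethod("show", "HCResult", function(object) {
    cat("HCResult:", ncol(object@components), "haplotype components over",
        nrow(object@components), "individuals\n")
})
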