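#' Build a reference palette by reference-vs-reference painting
#'
#' Paints the labelled reference panel against itself with the leave-one-out
#' scheme (own individual plus one individual from every other population
#' excluded) and averages each recipient individual's expected copied
#' lengths by population within recipient populations.  The resulting
#' npop x npop palette (rows = recipient population, columns = donor
#' population, entries in Morgans, rows summing to G) is the basis for NNLS
#' admixture estimation.
#'
#' @param ref_panel labelled reference \linkS4class{HaplotypePanel}; every
#'   population needs at least two individuals.
#' @param map the \linkS4class{GeneticMap}.
#' @param Q,Lmin,L0,lambda painting parameters (see
#'   \code{\link{paintTargets}}).
#' @return list with \code{palette} (npop x npop matrix), \code{b} (the
#'   per-individual copied-length matrix used to build it), and
#'   \code{painting} (the underlying \linkS4class{PaintingResult}).
#' @export
buildPalette <- function(ref_panel, map, Q = 10L, Lmin = 20L, L0 = NULL,
                         lambda = NULL) {
    pops <- popLabels(ref_panel)
    if (is.null(pops)) stop("reference panel must carry population labels")
    if (any(table(pops) < 2))
        stop("singleton population: leave-one-out painting impossible")
    pr <- paintTargets(ref_panel, NULL, map, mode = "rvr", Q = Q,
                       Lmin = Lmin, L0 = L0, lambda = lambda, probs = FALSE)
    b <- chunkLengthsByPop(pr, ref_panel)
    pal <- rowsum(b, pops) / as.vector(table(pops)[sort(unique(pops))])
    pal <- pal[sort(unique(pops)), sort(unique(pops)), drop = FALSE]
    list(palette = as.matrix(pal), b = b, painting = pr)
}

#' Non-negative least squares admixture estimation
#'
#' Describes an individual's expected copied lengths by population,
#' \code{b}, as a non-negative mixture of the palette's rows:
#' minimises \eqn{||A^T x - b||_2} subject to \eqn{x \ge 0} with the
#' Lawson-Hanson active-set algorithm, the palette rows acting as basis
#' vectors.
#'
#' @param palette npop x npop palette matrix (rows = recipient populations),
#'   from \code{\link{buildPalette}}.
#' @param b numeric vector (length npop) or matrix (individuals x npop) of
#'   expected copied lengths by donor population.
#' @return data.frame with one row per individual: normalised admixture
#'   coefficients per population (summing to 1), the raw coefficients
#'   (columns prefixed \code{raw.}), and the residual norm.
#' @export
nnlsAdmixture <- function(palette, b) {
    if (is.null(dim(b))) b <- matrix(b, 1, dimnames = list("ind1", names(b)))
    if (ncol(b) != nrow(palette))
        stop("b must have one entry per reference population")
    if (!is.null(colnames(b)) && !is.null(rownames(palette)))
        b <- b[, rownames(palette), drop = FALSE]
    A <- t(palette)                       # columns are palette rows
    out <- lapply(seq_len(nrow(b)), function(i) {
        bv <- as.numeric(b[i, ])
        if (all(bv == 0)) stop("all-zero copied-length vector for row ", i)
        fit <- pracma::lsqnonneg(A, bv)
        x <- fit$x
        c(x / sum(x), x, sqrt(sum((A %*% x - bv)^2)))
    })
    out <- do.call(rbind, out)
    npop <- nrow(palette)
    pops <- rownames(palette) %||% sprintf("pop%d", seq_len(npop))
    colnames(out) <- c(pops, paste0("raw.", pops), "residual")
    data.frame(out, row.names = rownames(b), check.names = FALSE)
}
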