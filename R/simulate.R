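#' Simulate an admixed cohort with recorded local-ancestry truth
#'
#' Frequency-based stand-in for forward population simulation, designed so
#' that painting, admixture estimation and the selection statistics can be
#' validated against exact truth.  Per population, founder allele
#' frequencies drift from shared ancestral frequencies under a
#' Balding-Nichols model parameterised by \code{Fst}; a small set of founder
#' haplotypes per population is drawn from those frequencies, and every
#' simulated haplotype is a mosaic of its population's founders (exponential
#' segment lengths along the genetic map), which creates the long shared
#' haplotypes the match engine relies on.  Target haplotypes are built from
#' \code{tGen} generations of admixture: ancestry breakpoints fall as a
#' Poisson process of rate \code{tGen} per Morgan, each segment draws its
#' source population from \code{admixProps} and its alleles from that
#' population's founder mosaic process; the segment labels are recorded as
#' truth.  Optional genotype error (random flips) and phase-switch error are
#' applied last.
#'
#' @param nPop number of source populations.
#' @param refSizes individuals per reference population (scalar or vector).
#' @param nTargets number of admixed target individuals.
#' @param admixProps admixture proportions (length nPop, summing to 1).
#' @param tGen generations since admixture (>= 1).
#' @param Fst drift between populations (default 0.05).
#' @param K number of SNPs.
#' @param chromLengthBP chromosome length in bp.
#' @param recombRate recombination rate in Morgans per bp (default 1e-8).
#' @param nFounders founder haplotypes per population (default 30).
#' @param founderSwitchRate founder mosaic switch rate per Morgan
#'   (default 100).
#' @param genoError per-allele flip probability (default 2e-4).
#' @param phaseError per-gap probability of a phase switch within target
#'   individuals (default 0).
#' @param conditionLoci optional data.frame with columns \code{cm} and
#'   \code{pop}: target haplotypes are resampled until their true ancestry
#'   at each given genetic position equals the given population index
#'   (a rejection-sampled stand-in for strong local selection on ancestry).
#' @param seed integer seed; the run is fully reproducible given it.
#' @return list with \code{ref} and \code{target}
#'   (\linkS4class{HaplotypePanel}s; the reference panel carries population
#'   labels popA, popB, ...), \code{map} (\linkS4class{GeneticMap}),
#'   \code{truth} (list: \code{labels} = target-hap x SNP matrix of true
#'   source population indices, \code{admixture} = per-target-individual
#'   true genome fraction per population, \code{segments} = data.frame of
#'   recorded ancestry segments), and \code{config}.
#' @export
simulateAdmixture <- function(nPop = 3, refSizes = 200, nTargets = 50,
                              admixProps = NULL, tGen = 13, Fst = 0.05,
                              K = 4000, chromLengthBP = 2e7,
                              recombRate = 1e-8, nFounders = 30,
                              founderSwitchRate = 100,
                              genoError = 2e-4, phaseError = 0,
                              conditionLoci = NULL, seed = 1) {
    stopifnot(nPop >= 1, tGen >= 1, K >= 2)
    if (is.null(admixProps)) admixProps <- rep(1 / nPop, nPop)
    stopifnot(length(admixProps) == nPop,
              abs(sum(admixProps) - 1) < 1e-8, all(admixProps >= 0))
    refSizes <- rep(refSizes, length.out = nPop)
    set.seed(seed)
    popNames <- paste0("pop", LETTERS[seq_len(nPop)])

    pos <- sort(sample.int(chromLengthBP - 1L, K))
    cm <- pos * recombRate * 100
    map <- new("GeneticMap", chrom = "1", positions = as.integer(pos),
               cm = cm, chromLengthCM = chromLengthBP * recombRate * 100)
    Gm <- totalMorgans(map)
    cmM <- cm / 100   # Morgans per SNP

    p0 <- runif(K, 0.1, 0.9)
    a <- (1 - Fst) / Fst
    freqs <- lapply(seq_len(nPop), function(p) rbeta(K, p0 * a, (1 - p0) * a))
    founders <- lapply(seq_len(nPop), function(p) {
        f <- matrix(rbinom(nFounders * K, 1L, rep(freqs[[p]], each = nFounders)),
                    nFounders, K)
        storage.mode(f) <- "integer"
        f
    })

    # mosaic of a population's founders over SNP range [from, to]
    popHapRange <- function(pop, from, to) {
        idx <- from:to
        brk <- .poissonPoints(cmM[from], cmM[to], founderSwitchRate)
        cuts <- findInterval(cmM[idx], brk) # segment number per SNP
        segs <- cuts - cuts[1]
        who <- sample.int(nFounders, max(segs) + 1L, replace = TRUE)
        founders[[pop]][cbind(who[segs + 1L], idx)]
    }

    refA <- matrix(0L, 2L * sum(refSizes), K)
    refPops <- character(sum(refSizes))
    r <- 0L
    for (p in seq_len(nPop)) {
        for (i in seq_len(refSizes[p])) {
            r <- r + 1L
            refPops[r] <- popNames[p]
            refA[2L * r - 1L, ] <- popHapRange(p, 1L, K)
            refA[2L * r, ] <- popHapRange(p, 1L, K)
        }
    }

    condIdx <- NULL
    if (!is.null(conditionLoci))
        condIdx <- vapply(conditionLoci$cm,
                          function(g) which.min(abs(cm - g)), 0L)

    nTgtHaps <- 2L * nTargets
    tgtA <- matrix(0L, nTgtHaps, K)
    labels <- matrix(0L, nTgtHaps, K)
    seglist <- vector("list", nTgtHaps)
    for (h in seq_len(nTgtHaps)) {
        repeat {
            brk <- .poissonPoints(cmM[1], cmM[K], tGen)
            segOf <- findInterval(cmM, brk) + 1L
            anc <- sample.int(nPop, max(segOf), replace = TRUE,
                              prob = admixProps)
            lab <- anc[segOf]
            if (is.null(condIdx) ||
                all(lab[condIdx] == conditionLoci$pop)) break
        }
        labels[h, ] <- lab
        runs <- rle(lab)
        ends <- cumsum(runs$lengths)
        starts <- c(1L, head(ends, -1L) + 1L)
        for (sgi in seq_along(starts))
            tgtA[h, starts[sgi]:ends[sgi]] <-
                popHapRange(runs$values[sgi], starts[sgi], ends[sgi])
        seglist[[h]] <- data.frame(hap = h, s = starts, e = ends,
                                   pop = runs$values)
    }

    # true genome-wide admixture fractions by genetic length, per individual
    w <- c(gapMorgans(map) / 2, 0) + c(0, gapMorgans(map) / 2)
    fracHap <- vapply(seq_len(nPop),
                      function(p) as.vector((labels == p) %*% w),
                      numeric(nTgtHaps)) / sum(w)
    fracHap <- matrix(fracHap, nTgtHaps, nPop)
    admixTrue <- (fracHap[seq(1, nTgtHaps, 2), , drop = FALSE] +
                  fracHap[seq(2, nTgtHaps, 2), , drop = FALSE]) / 2
    colnames(admixTrue) <- popNames

    if (genoError > 0) {
        flip <- function(A) {
            fl <- matrix(rbinom(length(A), 1L, genoError), nrow(A))
            Af <- abs(A - fl)
            storage.mode(Af) <- "integer"
            Af
        }
        refA <- flip(refA); tgtA <- flip(tgtA)
    }
    if (phaseError > 0) {
        for (i in seq_len(nTargets)) {
            sw <- cumsum(rbinom(K, 1L, phaseError)) %% 2L == 1L
            if (any(sw)) {
                h1 <- tgtA[2L * i - 1L, ]; h2 <- tgtA[2L * i, ]
                tgtA[2L * i - 1L, sw] <- h2[sw]
                tgtA[2L * i, sw] <- h1[sw]
            }
        }
    }

    ref <- new("HaplotypePanel", chrom = "1", positions = as.integer(pos),
               alleles = refA,
               sampleIds = sprintf("ref%03d", seq_len(sum(refSizes))),
               popLabels = refPops)
    target <- new("HaplotypePanel", chrom = "1", positions = as.integer(pos),
                  alleles = tgtA,
                  sampleIds = sprintf("tgt%03d", seq_len(nTargets)),
                  popLabels = character(0))
    list(ref = ref, target = target, map = map,
         truth = list(labels = labels, admixture = admixTrue,
                      segments = do.call(rbind, seglist), popNames = popNames),
         config = list(nPop = nPop, refSizes = refSizes, nTargets = nTargets,
                       admixProps = admixProps, tGen = tGen, Fst = Fst,
                       K = K, chromLengthBP = chromLengthBP,
                       recombRate = recombRate, G = Gm, seed = seed))
}

.poissonPoints <- function(from, to, rate) {
    # homogeneous Poisson process on [from, to] (Morgans); returns sorted
    # breakpoints (possibly empty)
    n <- rpois(1, rate * max(to - from, 0))
    sort(runif(n, from, to))
}

#' True local-ancestry dosage per individual
#'
#' @param truth truth component of \code{\link{simulateAdmixture}}.
#' @return list per target individual of npop x K dosage matrices with
#'   values 0, 0.5, 1.
#' @export
trueDosage <- function(truth) {
    nPop <- length(truth$popNames)
    nHap <- nrow(truth$labels)
    lapply(seq_len(nHap / 2L), function(i) {
        l1 <- truth$labels[2L * i - 1L, ]
        l2 <- truth$labels[2L * i, ]
        d <- matrix(0, nPop, ncol(truth$labels),
                    dimnames = list(truth$popNames, NULL))
        for (p in seq_len(nPop))
            d[p, ] <- ((l1 == p) + (l2 == p)) / 2
        d
    })
}

#' Dosage accuracy: mean squared correlation with the truth
#'
#' Per reference population, the squared Pearson correlation between the
#' estimated ancestry dosage (average of the individual's two haplotype
#' posteriors) and the true dosage (0/0.5/1), computed across all target
#' individuals and SNPs; the unweighted mean across populations is
#' returned.  Populations with zero truth variance are excluded with a
#' warning.
#'
#' @param painting a \linkS4class{PaintingResult} for the target panel (with
#'   stored posteriors), painted against the simulated reference.
#' @param truth truth component of \code{\link{simulateAdmixture}}.
#' @return list with \code{mean} (unweighted mean r2) and \code{perPop}.
#' @export
accuracyR2 <- function(painting, truth) {
    est <- paintingDosage(painting)
    tru <- trueDosage(truth)
    stopifnot(length(est) == length(tru))
    pops <- painting@pops
    r2 <- vapply(pops, function(pn) {
        p <- match(pn, truth$popNames)
        ev <- unlist(lapply(est, function(m) m[pn, ]))
        tv <- unlist(lapply(tru, function(m) m[p, ]))
        if (var(tv) == 0) return(NA_real_)
        cor(ev, tv)^2
    }, 0)
    if (anyNA(r2))
        warning("populations with zero truth variance excluded: ",
                paste(pops[is.na(r2)], collapse = ", "))
    list(mean = mean(r2, na.rm = TRUE), perPop = r2)
}

#' Best-guess accuracy of local ancestry
#'
#' Proportion of haplotype x SNP cells whose true source population has the
#' highest estimated posterior probability (ties broken towards the lowest
#' population index, counted separately).
#'
#' @inheritParams accuracyR2
#' @return list with \code{accuracy} and \code{tieRate}.
#' @export
accuracyBestGuess <- function(painting, truth) {
    pp <- popProbs(painting)
    stopifnot(length(pp) == nrow(truth$labels))
    ord <- match(painting@pops, truth$popNames)
    hits <- 0; ties <- 0; tot <- 0
    for (h in seq_along(pp)) {
        m <- pp[[h]]
        best <- max.col(t(m), ties.method = "first")
        ismax <- t(m) == m[cbind(best, seq_len(ncol(m)))]
        ties <- ties + sum(rowSums(ismax) > 1)
        hits <- hits + sum(ord[best] == truth$labels[h, ])
        tot <- tot + ncol(m)
    }
    list(accuracy = hits / tot, tieRate = ties / tot)
}
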