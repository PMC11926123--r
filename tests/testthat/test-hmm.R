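simpleMS <- function(df, nTgt, nRef, K) {
    df$lenSNP <- df$e - df$s + 1L
    if (is.null(df$lenCM)) df$lenCM <- 0
    if (is.null(df$imputed)) df$imputed <- FALSE
    new("MatchSet", matches = df, nTargetHaps = as.integer(nTgt),
        nRefHaps = as.integer(nRef), K = as.integer(K),
        Q = NA_integer_, Lmin = NA_integer_, L0 = NA_integer_)
}

mapFromCM <- function(cm) {
    pos <- as.integer(seq(1000, by = 1000, length.out = length(cm)))
    new("GeneticMap", chrom = "1", positions = pos, cm = cm,
        chromLengthCM = max(cm))
}

test_that("forward and backward boundary behaviour", {
    K <- 12
    map <- mapFromCM(seq(0, 1.1, by = 0.1))
    # exactly one matched donor at every SNP: normalised forward is 1
    ms1 <- simpleMS(data.frame(targetHap = 1L, refHap = 1L, s = 1L, e = K), 1, 4, K)
    fb <- sparseFB(ms1, 1, map, lambda = 10)
    expect_equal(fb$fcheck, rep(1, K))
    # last SNP backward is uniform over all N donors
    expect_equal(fb$bcheck[K], 1 / 4)
    # two donors matched everywhere with zero gaps: forward stays (0.5, 0.5)
    mapZ <- mapFromCM(rep(0, K))
    ms2 <- simpleMS(data.frame(targetHap = 1L, refHap = c(1L, 2L),
                               s = 1L, e = K), 1, 4, K)
    fb2 <- sparseFB(ms2, 1, mapZ, lambda = 10)
    expect_equal(fb2$fcheck, rep(0.5, 2 * K), tolerance = 1e-9)
    # huge gaps destroy linkage: backward equal across donors at every SNP
    mapB <- mapFromCM(seq(0, 11000, by = 1000))
    fb3 <- sparseFB(ms2, 1, mapB, lambda = 10)
    expect_equal(fb3$bcheck, rep(1 / 4, 2 * K), tolerance = 1e-9)
})

test_that("posterior is exact on degenerate and symmetric fixtures", {
    K <- 20
    map <- mapFromCM(seq(0, 1.9, by = 0.1))
    ms1 <- simpleMS(data.frame(targetHap = 1L, refHap = 3L, s = 1L, e = K), 1, 6, K)
    fb <- sparseFB(ms1, 1, map, lambda = 50,
                   donorPops = sprintf("h%d", 1:6))
    expect_equal(unname(fb$popProbs["h3", ]), rep(1, K))
    # symmetric two-donor fixture
    ms2 <- simpleMS(data.frame(targetHap = 1L, refHap = c(1L, 2L),
                               s = 1L, e = K), 1, 6, K)
    fb2 <- sparseFB(ms2, 1, map, lambda = 50,
                    donorPops = sprintf("h%d", 1:6))
    expect_equal(unname(fb2$popProbs["h1", ]), rep(0.5, K), tolerance = 1e-12)
})

test_that("sparse posterior, chunk lengths and counts match the dense oracle", {
    set.seed(201)
    worst <- c(0, 0, 0)
    for (rep in 1:8) {
        N <- sample(c(6, 10, 16), 1); K <- sample(c(80, 140, 200), 1)
        A <- correlatedAlleles(N, K)
        y <- A[sample(N, 1), ]
        poly <- which(colSums(A) > 0 & colSums(A) < N)
        flips <- sample(poly, min(5, length(poly)))
        y[flips] <- 1L - y[flips]
        pos <- sort(sample.int(1e6, K))
        map <- new("GeneticMap", chrom = "1", positions = as.integer(pos),
                   cm = pos * 1e-4, chromLengthCM = 100)
        lambda <- sample(c(50, 150, 400), 1)
        ref <- makePanel(A, pos = pos)
        tgt <- makePanel(rbind(y, y), pos = pos)
        idx <- buildPBWT(ref)
        ms <- reportQLongestMatches(idx, tgt, map, Q = 2L * N, Lmin = 1L)
        fb <- sparseFB(ms, 1, map, lambda, nDonors = N)
        o <- denseLS(A, y, gapMorgans(map), lambda, mu = 1e-9)
        sp <- densifyPosterior(fb, N, K)
        worst[1] <- max(worst[1], max(abs(sp - o$post)))
        worst[2] <- max(worst[2], max(abs(fb$lhat - o$lhat)))
        worst[3] <- max(worst[3], max(abs(fb$chat - o$chat)))
        # conservation identities
        expect_equal(sum(fb$lhat), totalMorgans(map), tolerance = 1e-9)
        expect_equal(max(abs(colSums(sp) - 1)), 0, tolerance = 1e-12)
    }
    expect_lt(worst[1], 1e-5)
    expect_lt(worst[2], 1e-5)
    expect_lt(worst[3], 1e-5)
})

test_that("chunk summaries behave on single-donor panels and small lambda", {
    K <- 30
    cm <- seq(0, 2.9, by = 0.1)
    map <- mapFromCM(cm)
    ms <- simpleMS(data.frame(targetHap = 1L, refHap = 1L, s = 1L, e = K), 1, 1, K)
    fb <- sparseFB(ms, 1, map, lambda = 80)
    # all copying comes from the single donor, total = G
    expect_equal(fb$lhat[1], totalMorgans(map), tolerance = 1e-12)
    # expected chunks: one opening chunk plus one per self-recombination
    rho <- exp(-80 * gapMorgans(map))
    expect_equal(fb$chat[1], 1 + sum(1 - rho), tolerance = 1e-9)
    # lambda -> 0: a single chunk
    fb0 <- sparseFB(ms, 1, map, lambda = 1e-6)
    expect_equal(fb0$chat[1], 1, tolerance = 1e-6)
})

test_that("lambda estimation follows the segmentation formula", {
    K <- 10
    cm <- seq(0, 50, length.out = K)  # G = 0.5 Morgans over 10 SNPs
    map <- mapFromCM(cm)
    # one full-length match: no breaks, floored estimate
    ms1 <- simpleMS(data.frame(targetHap = 1L, refHap = 1L, s = 1L, e = K), 1, 2, K)
    expect_equal(estimateLambda(ms1, map), 1e-6)
    # two abutting matches covering the chromosome: one break over 0.45 M
    ms2 <- simpleMS(data.frame(targetHap = 1L, refHap = c(1L, 2L),
                               s = c(1L, 6L), e = c(5L, 10L)), 1, 2, K)
    expect_equal(estimateLambda(ms2, map), 1 / totalMorgans(map))
    # G = 0.5 fixture from the definition: lambda = Nbreak / G = 1/0.5 = 2
    expect_equal(estimateLambda(ms2, map), 2, tolerance = 1e-9)
})

test_that("greedy minimum cover equals the DP oracle", {
    set.seed(202)
    for (rep in 1:25) {
        K <- sample(15:40, 1)
        n <- sample(3:12, 1)
        s <- sample(K, n, replace = TRUE)
        e <- pmin(K, s + sample(0:10, n, replace = TRUE))
        got <- haplopaint:::.minCoverSegments(s, e, K)
        expect_equal(got, minCoverDP(s, e, K))
    }
})

test_that("painting modes, exchangeability and lambda misspecification", {
    set.seed(203)
    sim <- simulateAdmixture(nPop = 2, refSizes = 12, nTargets = 4,
                             admixProps = c(.5, .5), tGen = 8, K = 600,
                             chromLengthBP = 3e6, seed = 9)
    # a target drawn verbatim from pop A: posterior mass on popA
    tgtA <- new("HaplotypePanel", chrom = "1",
                positions = positions(sim$ref),
                alleles = alleles(sim$ref)[1:2, , drop = FALSE],
                sampleIds = "cp", popLabels = character(0))
    prA <- paintTargets(sim$ref, tgtA, sim$map, mode = "tvr", Q = 8, Lmin = 15)
    expect_gt(mean(popProbs(prA)[[1]]["popA", ]), 0.95)

    # exchangeability: lowest-index individual of its population painted
    # rvr equals the same haplotypes painted tvr leave-one-out
    rvr <- paintTargets(sim$ref, NULL, sim$map, mode = "rvr", Q = 8,
                        Lmin = 15, lambda = 100)
    tvr <- paintTargets(sim$ref, tgtA, sim$map, mode = "tvr", Q = 8,
                        Lmin = 15, lambda = 100, leaveOneOut = TRUE)
    expect_equal(popProbs(tvr)[[1]], popProbs(rvr)[[1]], tolerance = 1e-12)
    expect_equal(unname(chunkLengths(tvr)[1, ]), unname(chunkLengths(rvr)[1, ]),
                 tolerance = 1e-12)

    # a grossly inflated lambda degrades accuracy
    sim2 <- simulateAdmixture(nPop = 2, refSizes = 15, nTargets = 8,
                              admixProps = c(.5, .5), tGen = 12, K = 800,
                              chromLengthBP = 4e6, seed = 9)
    good <- paintTargets(sim2$ref, sim2$target, sim2$map, mode = "tvr",
                         Q = 8, Lmin = 15)
    bad <- paintTargets(sim2$ref, sim2$target, sim2$map, mode = "tvr",
                        Q = 8, Lmin = 15, lambda = good@lambda * 300)
    expect_gt(accuracyBestGuess(good, sim2$truth)$accuracy,
              accuracyBestGuess(bad, sim2$truth)$accuracy)
    expect_gt(accuracyR2(good, sim2$truth)$mean,
              accuracyR2(bad, sim2$truth)$mean)
})

test_that("leave-one-out with singleton populations errors", {
    set.seed(204)
    sim <- simulateAdmixture(nPop = 2, refSizes = c(1, 3), nTargets = 2,
                             admixProps = c(.5, .5), tGen = 5, K = 200,
                             chromLengthBP = 1e6, seed = 10)
    expect_error(paintTargets(sim$ref, NULL, sim$map, mode = "rvr"),
                 "population")
})

test_that("increasing lambda favours locally matching donors (monotone locality)", {
    # donor 1 matches everywhere; donor 2 only on the left half
    K <- 40
    map <- mapFromCM(seq(0, 3.9, by = 0.1))
    df <- data.frame(targetHap = 1L, refHap = c(1L, 2L), s = c(1L, 1L),
                     e = c(K, 20L))
    ms <- simpleMS(df, 1, 2, K)
    right <- 21:40
    prev <- Inf
    for (lam in c(1, 10, 100, 500)) {
        fb <- sparseFB(ms, 1, map, lam, donorPops = c("d1", "d2"))
        competitor <- mean(fb$popProbs["d2", right])
        expect_lte(competitor, prev + 1e-12)
        prev <- competitor
    }
})

test_that("estimated lambda grows with time since admixture", {
    lams <- vapply(c(5, 30, 120), function(tg) {
        sim <- simulateAdmixture(nPop = 2, refSizes = 15, nTargets = 5,
                                 admixProps = c(.5, .5), tGen = tg, K = 800,
                                 chromLengthBP = 8e6, seed = 400 + tg)
        idx <- buildPBWT(sim$ref)
        ms <- reportQLongestMatches(idx, sim$target, sim$map, Q = 8L,
                                    Lmin = 15L)
        ms <- imputeEmptyPositions(ms, sim$map)
        estimateLambda(ms, sim$map)
    }, 0)
    expect_true(all(diff(lams) > 0))
})
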