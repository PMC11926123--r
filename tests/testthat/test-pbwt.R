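test_that("PBWT arrays equal the reversed-prefix sort oracle", {
    set.seed(101)
    for (rep in 1:5) {
        nh <- 8; K <- 32
        A <- matrix(rbinom(nh * K, 1L, .5), nh, K)
        panel <- makePanel(A)
        pb <- buildPBWT(panel)
        for (k in c(0, 1, 5, 17, K)) {
            if (k == 0) expOrd <- 1:nh
            else {
                keys <- vapply(1:nh, function(i)
                    paste(rev(A[i, 1:k]), collapse = ""), "")
                expOrd <- order(keys)      # stable, as is the PBWT radix pass
            }
            expect_equal(pb@prefix[, k + 1], expOrd)
            a <- expOrd
            for (i in 2:nh) {
                dexp <- k                   # empty-match convention
                if (k > 0)
                    for (ss in k:1) {
                        if (A[a[i], ss] == A[a[i - 1], ss]) dexp <- ss - 1
                        else break
                    }
                expect_equal(pb@divergence[i, k + 1], dexp + 1L)
            }
        }
    }
})

test_that("PBWT degenerate panels behave", {
    A <- matrix(rep(c(0L, 1L, 1L, 0L), 4), 4, 4)
    A[2, ] <- A[1, ]; A[3, ] <- A[1, ]; A[4, ] <- A[1, ]
    pb <- buildPBWT(makePanel(A))
    # identical haplotypes: divergence stays at the chromosome start
    expect_true(all(pb@divergence[-1, -1] == 1L))
    A1 <- matrix(c(0L, 1L, 0L, 1L), 2, 2)  # two haps, one sample
    pb1 <- buildPBWT(makePanel(A1))
    expect_equal(ncol(pb1@prefix), 3)
    expect_error(buildPBWT(makePanel(matrix(integer(0), 0, 0))))
})

test_that("long matches equal exhaustive enumeration, cross and within", {
    set.seed(102)
    for (rep in 1:6) {
        nh <- sample(c(4, 8, 12), 1); K <- sample(30:64, 1)
        L <- sample(1:6, 1)
        Aref <- correlatedAlleles(nh, K)
        Atgt <- correlatedAlleles(4, K)
        ref <- makePanel(Aref); tgt <- makePanel(Atgt)
        idx <- buildPBWT(ref)
        got <- matches(longMatches(idx, tgt, L))
        exp <- bruteLongMatches(Aref, Atgt, L)
        expect_setequal(matchKey(got), matchKey(exp))
        expect_false(anyDuplicated(matchKey(got)) > 0)
        # within-panel: both orientations of every unordered pair
        gotW <- matches(longMatches(idx, NULL, L))
        expW <- bruteLongMatches(Aref, Aref, L)
        expW <- expW[expW$targetHap != expW$refHap, ]
        expect_setequal(matchKey(gotW), matchKey(expW))
    }
})

test_that("raising L never adds matches and edge cases hold", {
    set.seed(103)
    Aref <- correlatedAlleles(8, 40)
    ref <- makePanel(Aref)
    tgt <- makePanel(Aref[c(1, 3), , drop = FALSE])
    idx <- buildPBWT(ref)
    k1 <- matchKey(matches(longMatches(idx, tgt, 2)))
    k2 <- matchKey(matches(longMatches(idx, tgt, 8)))
    expect_true(all(k2 %in% k1))
    # full-length copy found at L = K
    full <- matches(longMatches(idx, tgt, 40))
    expect_true(any(full$targetHap == 1 & full$refHap == 1 &
                    full$s == 1 & full$e == 40))
    expect_warning(ms <- longMatches(idx, tgt, 41), "exceeds")
    expect_equal(nrow(matches(ms)), 0)
})

test_that("set-maximal matches equal the containment-filter oracle", {
    set.seed(104)
    for (rep in 1:6) {
        nh <- 10; K <- 50
        A <- correlatedAlleles(nh, K)
        panel <- makePanel(A)
        got <- matches(setMaximalMatches(buildPBWT(panel)))
        exp <- bruteSetMaximal(A, A, excludeSelf = TRUE)
        expect_setequal(matchKey(got), matchKey(exp))
        # every SNP where the target agrees with someone is covered
        sm <- setMaximalMatches(buildPBWT(panel))
        for (t in 1:nh) {
            shared <- vapply(seq_len(K), function(k)
                any(A[-t, k] == A[t, k]), TRUE)
            expect_true(all(matchCoverage(sm, t)[shared] >= 1))
        }
    }
    # target identical to a reference haplotype: one full-length match
    A <- correlatedAlleles(6, 30)
    ref <- makePanel(A)
    tgt <- makePanel(A[c(2, 4), , drop = FALSE])
    got <- matches(setMaximalMatches(buildPBWT(ref), tgt))
    g1 <- got[got$targetHap == 1 & got$s == 1 & got$e == 30, ]
    expect_true(2 %in% g1$refHap)
    # cross-panel agrees with the oracle too
    exp <- bruteSetMaximal(A, A[c(2, 4), , drop = FALSE])
    expect_setequal(matchKey(got), matchKey(exp))
    # nothing shared: all-1 targets vs constant all-0 panel
    Ac <- matrix(0L, 4, 20)
    gotNone <- matches(setMaximalMatches(buildPBWT(makePanel(Ac)),
                                         makePanel(matrix(1L, 2, 20))))
    expect_equal(nrow(gotNone), 0)
})

test_that("Q-longest selection matches the staged and greedy oracles", {
    set.seed(105)
    sim <- simulateAdmixture(nPop = 3, refSizes = 8, nTargets = 3,
                             admixProps = c(.3, .4, .3), tGen = 8, K = 400,
                             chromLengthBP = 2e6, seed = 77)
    idx <- buildPBWT(sim$ref)
    Q <- 5L; Lmin <- 10L
    ms <- reportQLongestMatches(idx, sim$target, sim$map, Q = Q, Lmin = Lmin)
    raw <- matches(longMatches(idx, sim$target, Lmin, map = sim$map))
    for (t in seq_len(ms@nTargetHaps)) {
        mt <- raw[raw$targetHap == t, , drop = FALSE]
        kept <- qlongestOracleStaged(mt, ms@K, Q, Lmin, ms@L0)
        got <- matches(ms); got <- got[got$targetHap == t, , drop = FALSE]
        expect_setequal(matchKey(got), matchKey(mt[kept, , drop = FALSE]))
        # the coverage property must hold on any map:
        # min(kept coverage, Q) == min(full coverage, Q) at every SNP
        covAll <- integer(ms@K)
        for (i in seq_len(nrow(mt))) {
            rng <- mt$s[i]:mt$e[i]
            covAll[rng] <- covAll[rng] + 1L
        }
        covKept <- matchCoverage(ms, t)
        expect_equal(pmin(covKept, Q), pmin(covAll, Q))
        expect_true(all(covKept <= covAll))
    }
})

test_that("Q-longest equals the pure greedy oracle under a uniform map", {
    set.seed(106)
    A <- correlatedAlleles(16, 200)
    ref <- makePanel(A[1:12, ])
    tgt <- makePanel(A[13:16, ])
    map <- uniformMap(ref)
    idx <- buildPBWT(ref)
    Q <- 3L; Lmin <- 5L
    ms <- reportQLongestMatches(idx, tgt, map, Q = Q, Lmin = Lmin)
    raw <- matches(longMatches(idx, tgt, Lmin, map = map))
    for (t in 1:4) {
        mt <- raw[raw$targetHap == t, , drop = FALSE]
        kept <- qlongestOracleGreedy(mt, ms@K, Q)
        got <- matches(ms); got <- got[got$targetHap == t, , drop = FALSE]
        expect_setequal(matchKey(got), matchKey(mt[kept, , drop = FALSE]))
    }
    # Q=1, target a verbatim copy, L0 >= K: exactly the full-length match
    tgt1 <- makePanel(A[c(1, 2), , drop = FALSE])
    ms1 <- reportQLongestMatches(idx, tgt1, map, Q = 1L, Lmin = 5L, L0 = 256L)
    m1 <- matches(ms1)
    m1 <- m1[m1$targetHap == 1, ]
    expect_equal(nrow(m1), 1)
    expect_equal(unname(unlist(m1[1, c("refHap", "s", "e")])), c(1, 1, 200))
})

test_that("imputation fills matchless SNPs from the nearest covered SNP", {
    df <- data.frame(targetHap = 1L, refHap = c(1L, 2L), s = c(1L, 8L),
                     e = c(3L, 10L), lenSNP = 3L, lenCM = 0.2,
                     imputed = FALSE)
    ms <- new("MatchSet", matches = df, nTargetHaps = 1L, nRefHaps = 2L,
              K = 10L, Q = NA_integer_, Lmin = NA_integer_, L0 = NA_integer_)
    pos <- c(10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L, 100L)
    map <- new("GeneticMap", chrom = "1", positions = pos, cm = pos / 10,
               chromLengthCM = 10)
    imp <- imputeEmptyPositions(ms, map)
    m <- matches(imp)
    expect_true(all(matchCoverage(imp, 1) >= 1))
    # SNP 4,5 nearer to covered SNP 3 (left); SNP 5 is closer to 3? cm 5 vs 8:
    # |5-3|=2 (in snps) left distance 0.2? cm(5)=5, cm(3)=3 -> 2; cm(8)=8 -> 3: left
    i5 <- m[m$imputed & m$s == 5, ]
    expect_equal(i5$refHap, 1L)           # donors of SNP 3
    i6 <- m[m$imputed & m$s == 6, ]       # equidistant between 3 and 8? 3 vs 2 -> right
    expect_equal(i6$refHap, 2L)
    # exact tie goes left: SNP at cm 5.5 between covered 3 and 8
    # (construct: covered SNPs at cm 3 and 8, empty at 5.5)
    ms2 <- new("MatchSet", matches = df, nTargetHaps = 1L, nRefHaps = 2L,
               K = 10L, Q = NA_integer_, Lmin = NA_integer_, L0 = NA_integer_)
    cm2 <- c(1, 2, 3, 4, 5.5, 5.5, 7, 8, 9, 10)
    map2 <- new("GeneticMap", chrom = "1", positions = pos, cm = cm2,
                chromLengthCM = 10)
    imp2 <- imputeEmptyPositions(ms2, map2)
    i5b <- matches(imp2)
    i5b <- i5b[i5b$imputed & i5b$s == 5, ]   # cm 5.5: tie |5.5-3|=2.5, |8-5.5|=2.5
    expect_equal(i5b$refHap, 1L)
    # no empty SNPs: identity
    full <- data.frame(targetHap = 1L, refHap = 1L, s = 1L, e = 10L,
                       lenSNP = 10L, lenCM = 1, imputed = FALSE)
    msF <- new("MatchSet", matches = full, nTargetHaps = 1L, nRefHaps = 1L,
               K = 10L, Q = NA_integer_, Lmin = NA_integer_, L0 = NA_integer_)
    expect_identical(matches(imputeEmptyPositions(msF, map)), full)
    # fully matchless target errors
    none <- full[0, ]
    msN <- new("MatchSet", matches = none, nTargetHaps = 1L, nRefHaps = 1L,
               K = 10L, Q = NA_integer_, Lmin = NA_integer_, L0 = NA_integer_)
    expect_error(imputeEmptyPositions(msN, map), "no matches")
})

test_that("nearest-covered choice matches a linear-scan oracle on a masked region", {
    set.seed(107)
    K <- 60L
    cm <- cumsum(runif(K, 0.01, 0.3)); pos <- seq_len(K) * 100L
    map <- new("GeneticMap", chrom = "1", positions = pos, cm = cm,
               chromLengthCM = max(cm))
    cov <- sort(sample(K, 30))
    df <- data.frame(targetHap = 1L, refHap = seq_along(cov), s = cov, e = cov,
                     lenSNP = 1L, lenCM = 0, imputed = FALSE)
    ms <- new("MatchSet", matches = df, nTargetHaps = 1L,
              nRefHaps = length(cov), K = K, Q = NA_integer_,
              Lmin = NA_integer_, L0 = NA_integer_)
    imp <- imputeEmptyPositions(ms, map)
    m <- matches(imp)
    for (k in setdiff(seq_len(K), cov)) {
        d <- abs(cm[cov] - cm[k])
        best <- cov[which(d == min(d))]
        src <- if (length(best) > 1) min(best) else best  # tie -> left
        got <- m[m$imputed & m$s == k, "refHap"]
        expect_equal(got, which(cov == src))
    }
})
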