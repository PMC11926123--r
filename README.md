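# haplopaint

Sparse chromosome painting for phased biallelic haplotypes: fast local
ancestry inference, genome-wide haplotype structure, admixture estimation
and ancestry-based selection scans.

## What it does

Chromosome painting expresses each haplotype of a study individual as a
probabilistic mosaic of "donor" haplotypes from a labelled reference panel,
under the Li & Stephens copying hidden Markov model.  Evaluating that model
densely costs O(NK) per target haplotype (N reference haplotypes, K SNPs),
which does not scale to large panels.  `haplopaint` implements the sparse
strategy:

1. **PBWT match engine** — a positional Burrows–Wheeler transform finds, at
   every SNP, at least Q of the longest exact haplotype matches to the
   panel (`reportQLongestMatches()`, with set-maximal and long-match
   queries also exposed).
2. **Sparse copying HMM** — the forward–backward recursions with mutation
   probability μ → 0 are evaluated only on matched donors, in normalised
   form with log-accumulated normalisers (`paintTargets()`).  Outputs per
   target haplotype: the per-SNP posterior over donor populations, the
   expected copied chunk length l̂_i (Morgans) and chunk count ĉ_i per
   donor, and a segmentation-based estimate of the recombination scaling
   constant λ (ρ_j = exp(−λ g_j), λ* = N_break / Σ g_j).
3. **Fast all-vs-all painter** — set-maximal matches scored with the
   quadratic weight w_jk = (k − s_jk)(e_jk − k), aggregated into a sparse
   coancestry matrix A whose rows sum to the genome's genetic length;
   haplotype components are the leading columns of U√D from the SVD of
   log10(A + 1) (`avaPaintScores()`, `aggregateCoancestry()`,
   `haplotypeComponents()`).
4. **Admixture by NNLS** — reference-vs-reference painting builds a
   population palette; individuals are decomposed as non-negative mixtures
   of palette rows, min‖Aᵀx − b‖₂ s.t. x ≥ 0 (`buildPalette()`,
   `nnlsAdmixture()`).
5. **Selection statistics** — LDA (correlation of ancestry between SNP
   pairs via total-variation distances with an exact pairwise null), its
   ±4 cM integral LDAS with upper/lower integration bounds and density QC,
   and the ancestry anomaly score AAS with Gamma-calibrated p-values
   (`ldasTrack()`, `aasTrack()`, `classifySignals()`).  Low LDAS flags
   unexpectedly short ancestry haplotypes; high AAS flags SNPs whose mean
   ancestry departs from the genome-wide profile.
6. **Simulator with truth** — `simulateAdmixture()` generates drifted
   populations, founder-mosaic haplotypes and t-generation admixed targets
   with recorded ancestry segments, so every pipeline stage can be
   validated against exact truth (`accuracyR2()`, `accuracyBestGuess()`).

Input formats: phased VCF (`readVCF()`), ChromoPainter-style phase format
(`readPhase()`), two/three-column genetic maps, two-column population
labels.  A thin command-line wrapper lives in
`inst/scripts/haplopaint-cli.R`.

## Worked example

```r
library(haplopaint)
sim <- simulateAdmixture(nPop = 3, refSizes = 50, nTargets = 10,
                         admixProps = c(.2, .5, .3), tGen = 13, K = 2000,
                         chromLengthBP = 2e7, seed = 42)
pr <- paintTargets(sim$ref, sim$target, sim$map, mode = "tvr",
                   Q = 10, Lmin = 20)
pr
#> PaintingResult: 20 target haplotypes, 3 donor populations, lambda = 125.671
#>   G = 0.199728 Morgans; posteriors stored
accuracyBestGuess(pr, sim$truth)$accuracy   # 0.992
accuracyR2(pr, sim$truth)$mean              # 0.968
```

λ ≈ 126 is the recombination scaling estimated from the match segmentation
(13 generations of admixture plus within-population haplotype mosaic
structure); the posterior assigns the true source population at 99.2% of
haplotype × SNP cells, and ancestry dosages correlate with the exact truth
at r² ≈ 0.97.  Admixture fractions by NNLS:

```r
pal <- buildPalette(sim$ref, sim$map, Q = 10, Lmin = 20)
round(pal$palette, 4)
#>        popA   popB   popC
#> popA 0.1991 0.0004 0.0002
#> popB 0.0001 0.1992 0.0005
#> popC 0.0003 0.0002 0.1993
prL <- paintTargets(sim$ref, sim$target, sim$map, mode = "tvr",
                    leaveOneOut = TRUE, probs = FALSE, Q = 10, Lmin = 20)
est <- nnlsAdmixture(pal$palette, chunkLengthsByPop(prL, sim$ref))
head(est[, 1:3], 3)
#>         popA  popB  popC     (true: 0.111 0.383 0.506
#> tgt001 0.113 0.378 0.509             0.195 0.568 0.237
#> tgt002 0.201 0.569 0.230             0.038 0.382 0.580)
#> tgt003 0.042 0.381 0.577
```

The palette is strongly diagonal (each population copies ~0.199 of its
0.1997-Morgan genome from itself under leave-one-out painting), and the
estimated mixture coefficients track the per-individual truth to within a
few percent.

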