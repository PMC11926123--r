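---
title: "Sparse chromosome painting: models, parameters and design choices"
author: "haplopaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse chromosome painting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopaint)
```

## The problem

Chromosome painting describes each haplotype of an admixed individual as a
probabilistic mosaic of "donor" haplotypes from a labelled reference panel.
The per-SNP posterior over donor populations is the local ancestry estimate;
its genome-wide aggregates (expected copied chunk lengths and counts per
donor) feed admixture estimation, population-structure summaries and
selection scans.  The classical copying model is the Li & Stephens hidden
Markov model, whose cost per target haplotype is O(NK) for N reference
haplotypes and K SNPs — prohibitive for biobank-scale panels.  This package
implements the sparse formulation: a positional Burrows–Wheeler transform
(PBWT) first extracts, at every SNP, a small set of the longest exact
haplotype matches, and the HMM is then evaluated only on those matched
donors, reducing the per-SNP cost from O(N) to roughly O(Q), with Q the
target number of matches per site.

## Match extraction

`buildPBWT()` constructs the positional prefix and divergence arrays; all
match queries sweep the panel column by column in O(NK):

* `longMatches()` reports every maximal exact match of at least L SNPs
  between target and panel haplotypes (both-panels sweep with block
  enumeration; matches are reported once, at the site where they stop
  extending).
* `setMaximalMatches()` reports, for each target haplotype and position,
  only the locally longest matches (used by the fast all-vs-all painter).
* `reportQLongestMatches()` aims for at least Q matches at every SNP
  while preferring the longest: stage 1 collects matches of at least
  `Lmin` SNPs in halving length bands starting from `L0`, keeping a
  band's match only if it covers a SNP that is still deficient; stage 2
  sorts candidates by descending genetic length and greedily keeps a
  match iff it covers a SNP with fewer than Q kept matches.  We implement
  stage 1 as one sweep at `Lmin` followed by in-memory band selection; the
  output set is identical to re-running the PBWT per band.

Defaults `Q = 10`, `Lmin = 20` SNPs follow common practice for panels of
this density; `L0 = 2^ceiling(log2(K/16))` starts above the longest matches
usually present so only a few halving rounds run.  Stage-2 ties in genetic
length are broken by SNP length, then donor index, then start position, so
results are reproducible across platforms.

SNPs that end up with *no* match (possible when `Lmin` filters everything
out) would zero the forward recursion; `imputeEmptyPositions()` copies the
donor set of the nearest covered SNP in genetic distance (ties to the left)
into such SNPs, as single-SNP rows flagged `imputed`.

## The sparse copying model

With match indicator m_ij (donor i matches the target at SNP j), mutation
probability mu set exactly to 0, gap g_j in Morgans between SNPs j and j+1,
and recombination scaling constant lambda, the transition mixes "stay"
(probability rho_j = exp(-lambda g_j)) with "jump to a uniform donor"
((1-rho_j)/N each).  Both recursions are kept normalised, with the
normalisers F_j, B_j accumulated in log space:

* forward: f*_ij = rho_{j-1} f_{i,j-1} + (1-rho_{j-1})/N on the matched
  set s_j, zero elsewhere; F_j renormalises.
* backward: matched donors at j+1 get rho_j b_{i,j+1} + default, everyone
  else shares the default (1-rho_j)/N * ctilde_{j+1}; this is why the
  sparse pass never touches unmatched donors.

The posterior at SNP j is proportional to f_ij b_ij on s_j.  Expected
copied chunk lengths use the trapezoid of the posterior over the genetic
map (so per-target lengths always sum to the map length G — an identity the
tests assert to 1e-9), and expected chunk counts subtract the probability
of "same donor, no recombination" transitions from the marginals.  All
F/B products enter as exp of log-cumulative differences; no probability is
ever formed as a raw product over SNPs.  A technical floor: map gaps of
exactly zero are clamped to 1e-12 Morgans inside the HMM so that donors
entering the matched set across a zero-gap remain reachable.

Under the self-transition convention of the copying model, a recombination
that lands back on the same donor opens a new chunk; a single-donor
chromosome therefore has expected chunk count 1 + sum_j (1 - rho_j), which
tends to 1 as lambda tends to 0.  The dense-oracle tests pin this behaviour.

`lambda` is by default estimated from the matches themselves: with mu = 0
the most probable copying path stays inside stored matches, so the minimum
number of donor segments tiling the chromosome (greedy farthest-reach
interval cover, which is optimal for intervals) gives N_break = N_seg - 1
and lambda* = N_break / G, averaged over target haplotypes and floored at
1e-6 for the degenerate single-match case.  Imputed matches are excluded
from the cover; a region covered only by imputed matches is jumped, the
jump counting as a segment boundary.

### Painting modes and exchangeability

`paintTargets()` supports target-vs-reference (optionally leave-one-out),
reference-vs-reference (panel painting: own individual plus the
lowest-indexed individual of every other population excluded) and
all-vs-all (own individual excluded).  The "lowest index" rule makes
leave-one-out deterministic; because the same individuals are excluded, a
reference individual painted in panel mode and the same haplotypes
presented as an external target receive *identical* tracks whenever that
individual is the lowest-indexed of its population — the exchangeability
property the modes are designed around, asserted exactly in the tests.

## Fast all-vs-all painting and haplotype components

`avaPaintScores()` skips the HMM entirely: each haplotype is scored against
its set-maximal matches with the weight w_jk = (k - s_jk)(e_jk - k), which
grows quadratically with match length at the match midpoint, normalised per
SNP.  When every covering match starts or ends exactly at k the weight is
0/0; we fall back to a uniform weight over covering donors.  Per-SNP scores
are summed and scaled by g/K (map length in cM over SNP count) so each
haplotype distributes exactly g cM across donors; `aggregateCoancestry()`
folds haplotypes into individuals — recipient rows averaged, donor columns
summed — so each individual's row of the coancestry matrix A sums to the
genome length G in cM with a zero diagonal.  `haplotypeComponents()` takes
the SVD of log10(A + 1) and returns U sqrt(D) columns ("haplotype
components"), with each component's largest-magnitude loading made
positive.  At package scale (thousands of individuals) the dense exact SVD
is appropriate; truly biobank-sized panels would substitute a truncated
sparse solver without changing the interface.

Set-maximal weights are a deliberate approximation: they misattribute
locally when ancestry is ambiguous, but the errors self-average genome-wide;
the test suite checks that population-aggregated genome-wide scores
correlate strongly with the HMM's chunk lengths while making no claim about
per-SNP accuracy of this mode.

## Admixture estimation

`buildPalette()` averages reference-vs-reference copied chunk lengths
within recipient populations into an npop x npop palette (rows sum to G).
`nnlsAdmixture()` solves min ||A^T x - b|| subject to x >= 0 with the
Lawson–Hanson active-set algorithm (`pracma::lsqnonneg`), b being an
individual's copied length per donor population (haplotype pair averaged).
Coefficients are reported both raw and normalised to sum 1; the normalised
vector is the headline admixture estimate.

## Selection statistics: LDA, LDAS, AAS

The ancestry field is the n_hap x K x npop array of per-haplotype posterior
vectors.  LDA between SNPs j and l compares the mean total-variation
distance between a haplotype's own paintings at j and l (D_obs) with the
exact mean over all ordered haplotype pairs (D_null):
LDA = (D_null - D_obs)/D_null, defined as 0 when D_null = 0.  D_null is the
expectation of the usual permutation null, but computed exactly as a
U-statistic with sorted-column prefix sums (O(n) per population after an
O(n log n) presort), so the statistic is deterministic; the tests confirm
the Monte-Carlo permutation estimate agrees within its standard error.  The
exact formula is a reconstruction satisfying the published properties
(range, null behaviour), not a verbatim port of the companion method.

LDAS integrates LDA around each SNP over a +/-X cM window (default X = 4,
beyond which pairwise LDA is effectively zero), treating LDA as piecewise
linear in genetic distance, with the near-chromosome-end portions reflected
back inside.  Replacing the interpolant by step functions taking the
larger/smaller neighbouring value yields upper/lower bounds; for the lower
bound the chromosome ends are pinned to zero LDA.  Between the outermost
SNP in the window and the window edge the integrand is continued flat using
the first SNP beyond the edge for interpolation where one exists.  The
bound difference, normalised by the cohort's mean LDAS, is the integration
error; QC removes SNPs with normalised error >= delta (0.3) or with any
0.5 cM distance band within 3 cM holding fewer than theta (10) SNPs.  Low
LDAS is converted to a one-sided normal p-value over QC-passing SNPs.

AAS sums, over ancestries, the squared z-scores of a SNP's mean ancestry
against the genome-wide mean and standard deviation; p-values come from a
Gamma distribution fitted to the genome-wide AAS by the method of moments
(an all-constant ancestry is dropped with a warning; if nothing varies the
score is zero everywhere).  `classifySignals()` labels candidate SNPs as
shared or cohort-specific with the 1e-6/0.05/0.1 (LDAS) and
1e-50/1e-10/1e-5 (AAS) threshold triples.

## The simulator and what passing tests do (and do not) show

`simulateAdmixture()` is a frequency-based stand-in for forward simulation,
chosen so that truth is exact by construction: population founder
frequencies drift from shared ancestral frequencies (Balding–Nichols,
default Fst 0.05); a small founder set per population (default 30) supplies
long shared haplotypes via an exponential mosaic (default 100 switches per
Morgan); target haplotypes recombine for tGen generations (Poisson
breakpoints on the genetic map, default rate 1e-8 Morgans/bp over 20 Mb),
each segment's source population drawn from the admixture proportions and
recorded as truth.  Genotype error (default 2e-4) flips alleles; optional
phase-switch error swaps haplotype tails.  `conditionLoci` rejection-samples
target ancestries until chosen loci carry chosen ancestries — the stand-in
for strong local selection used by the positive-control tests.

What this emulates well: long shared haplotypes, drift-separated
populations, Poisson ancestry block lengths, exact truth labels.  What it
does not: coalescent depth structure, incomplete lineage sorting, gene
conversion, SNP ascertainment.  Accuracy numbers on this generator are
therefore comparable to forward-simulation results in regime, not in value,
and the acceptance checks are phrased as properties (conservation, oracle
equivalence, calibration, ordering) rather than as reproduction of any
particular published figure.

Problem sizes used by the checks were chosen to run comfortably on a single
CPU: the dense-oracle comparisons use panels up to 16 haplotypes by 200
SNPs (where the mu = 1e-9 dense reference is exact to ~1e-6); admixture
recovery uses 200 reference individuals per population, 50 targets and
4000 SNPs; the drift-null selection scan uses 5 populations and 10,000 SNPs
over 250 cM (40 SNPs/cM, comfortably above the density QC); the two-locus
positive control uses 10 independent seeds.

## Numerical and convention notes

* SNP indices and match intervals are 1-based and inclusive at both ends
  at the R surface (0-based internally in the compiled sweeps).
* Match tables are plain data.frames inside S4 containers with validity
  checks; every container prints a compact summary via `show()`.
* The coancestry matrix and its row-sum invariant are in cM; HMM chunk
  lengths are in Morgans.
* Phase-format and genetic-map parsers are strict: non-binary alleles,
  non-ascending positions, and (by default) missing or unphased VCF
  genotypes are errors, since the copying model has no missing-data state.
* Output probability tracks print at 4 decimal places by default, with a
  row-sum check (1e-6) before rounding.
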