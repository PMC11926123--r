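Package: haplopaint
Title: Sparse Chromosome Painting, Haplotype Components and Ancestry Selection Scans
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fast local ancestry inference for phased biallelic haplotypes.
    Implements a positional Burrows-Wheeler transform (PBWT) match engine with
    set-maximal, long-match and Q-longest match queries; a sparse Li & Stephens
    copying hidden Markov model driven by those matches, with per-SNP ancestry
    posteriors, expected copied chunk lengths and counts, and Viterbi-style
    estimation of the recombination scaling constant; set-maximal all-vs-all
    painting with quadratic match-length weights, genome-wide coancestry
    aggregation and haplotype components via SVD; non-negative least squares
    admixture estimation from painting palettes; linkage disequilibrium of
    ancestry (LDA/LDAS) and ancestry anomaly score (AAS) selection statistics
    with quality control and shared/specific signal classification; and an
    admixture simulator with recorded local-ancestry truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    pracma,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, SNP, StatisticalMethod, PopulationGenetics
RoxygenNote: 7.3.3
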