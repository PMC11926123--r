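#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Linkage disequilibrium of ancestry between SNP pairs.
//
// P is an n x K x npop array of per-haplotype ancestry probabilities.
// For SNPs j and l, with d_i the total-variation distance between haplotype
// i's ancestry vectors at j and l, LDA(j,l) = (Dnull - Dobs)/Dnull where
// Dobs = mean_i d_i and Dnull is the exact mean of d over all ordered
// haplotype pairs (i at j, i' at l, i != i'), a U-statistic equal to the
// expectation of the permutation null.
//
// Pairs are emitted for all j < l with cm[l] - cm[j] <= X, plus one extra
// flanking SNP per side of each window so integrals can be clipped exactly
// at the window boundary.
// [[Rcpp::export]]
DataFrame cpp_lda_pairs(NumericVector P, NumericVector cm, double X) {
    IntegerVector dim = P.attr("dim");
    const int n = dim[0], K = dim[1], npop = dim[2];
    const double *p = P.begin();
    const size_t colstride = (size_t)n;            // within pop slab
    const size_t popstride = (size_t)n * K;

    // sorted columns + prefix sums per (snp, pop)
    std::vector<double> srt((size_t)n * K * npop);
    std::vector<double> pre((size_t)(n + 1) * K * npop);
    for (int a = 0; a < npop; ++a)
        for (int j = 0; j < K; ++j) {
            const double *col = p + a * popstride + j * colstride;
            double *dst = &srt[(size_t)(a * K + j) * n];
            std::copy(col, col + n, dst);
            std::sort(dst, dst + n);
            double *pr = &pre[(size_t)(a * K + j) * (n + 1)];
            pr[0] = 0.0;
            for (int i = 0; i < n; ++i) pr[i + 1] = pr[i] + dst[i];
        }

    std::vector<int> oj, ol;
    std::vector<double> ov;
    for (int j = 0; j < K; ++j) {
        int lmax = j;
        while (lmax + 1 < K && cm[lmax + 1] - cm[j] <= X) ++lmax;
        if (lmax + 1 < K) ++lmax;                   // one flanking SNP
        for (int l = j + 1; l <= lmax; ++l) {
            double dobsTot = 0.0;                   // sum_i sum_a |x - y|
            double crossTot = 0.0;                  // sum_{i,i'} sum_a |x_i - y_i'|
            for (int a = 0; a < npop; ++a) {
                const double *xj = p + a * popstride + j * colstride;
                const double *xl = p + a * popstride + l * colstride;
                for (int i = 0; i < n; ++i) dobsTot += std::fabs(xj[i] - xl[i]);
                const double *sx = &srt[(size_t)(a * K + j) * n];
                const double *sy = &srt[(size_t)(a * K + l) * n];
                const double *px = &pre[(size_t)(a * K + j) * (n + 1)];
                const double sxTot = px[n];
                int c = 0;
                for (int i = 0; i < n; ++i) {
                    const double y = sy[i];
                    while (c < n && sx[c] <= y) ++c;
                    crossTot += y * c - px[c] + (sxTot - px[c]) - y * (n - c);
                }
            }
            const double dobs = 0.5 * dobsTot / n;
            const double dnull = 0.5 * (crossTot - dobsTot) / ((double)n * (n - 1));
            const double lda = dnull > 0 ? (dnull - dobs) / dnull : 0.0;
            oj.push_back(j + 1); ol.push_back(l + 1); ov.push_back(lda);
        }
    }
    return DataFrame::create(_["j"] = IntegerVector(oj.begin(), oj.end()),
                             _["l"] = IntegerVector(ol.begin(), ol.end()),
                             _["lda"] = NumericVector(ov.begin(), ov.end()));
}
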