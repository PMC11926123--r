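#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Genome-wide scores from set-maximal matches with the quadratic weight
// w_jk = (k - s_jk)(e_jk - k) for a match [s,e] covering SNP k, normalised
// per SNP: p_jk = w_jk / sum_l w_lk.  When every covering match starts or
// ends exactly at k (all weights zero) the weight falls back to uniform over
// the covering donors.  SNPs with no covering match borrow the donors of the
// nearest covered SNP in genetic distance (ties to the left).
//
// Matches are for ONE target haplotype: refHap (0-based donor), s, e 0-based
// inclusive.  Returns the genome-wide accumulation sum_k p_jk per donor as a
// sparse (donor, score) pair, plus optionally the per-SNP sparse scores.
// [[Rcpp::export]]
List cpp_ava_scores(IntegerVector refHap, IntegerVector s, IntegerVector e,
                    int K, int N, NumericVector cm, bool perSite) {
    const int n = refHap.size();
    // sweep with add/remove events
    std::vector<std::vector<int>> addAt(K), remAt(K);
    for (int i = 0; i < n; ++i) {
        addAt[s[i]].push_back(i);
        remAt[e[i]].push_back(i);
    }
    std::vector<double> acc(N, 0.0);
    std::vector<int> active;
    std::vector<int> uncovered;
    List siteDonor(perSite ? K : 0), siteProb(perSite ? K : 0);

    for (int k = 0; k < K; ++k) {
        for (int i : addAt[k]) active.push_back(i);
        if (active.empty()) {
            uncovered.push_back(k);
        } else {
            double wsum = 0.0;
            for (int i : active)
                wsum += (double)(k - s[i]) * (double)(e[i] - k);
            std::vector<double> pr(active.size());
            if (wsum > 0) {
                for (size_t t = 0; t < active.size(); ++t) {
                    int i = active[t];
                    pr[t] = (double)(k - s[i]) * (double)(e[i] - k) / wsum;
                }
            } else {
                for (size_t t = 0; t < active.size(); ++t)
                    pr[t] = 1.0 / active.size();
            }
            for (size_t t = 0; t < active.size(); ++t)
                acc[refHap[active[t]]] += pr[t];
            if (perSite) {
                IntegerVector dn(active.size());
                NumericVector pv(active.size());
                for (size_t t = 0; t < active.size(); ++t) {
                    dn[t] = refHap[active[t]] + 1;
                    pv[t] = pr[t];
                }
                siteDonor[k] = dn; siteProb[k] = pv;
            }
        }
        if (!remAt[k].empty()) {
            std::vector<int> keep;
            keep.reserve(active.size());
            std::vector<char> drop(n, 0);
            for (int i : remAt[k]) drop[i] = 1;
            for (int i : active) if (!drop[i]) keep.push_back(i);
            active.swap(keep);
        }
    }

    // impute uncovered SNPs from nearest covered SNP in cM (tie -> left)
    if (!uncovered.empty() && (int)uncovered.size() < K) {
        std::vector<char> cov(K, 1);
        for (int k : uncovered) cov[k] = 0;
        // for each uncovered k find nearest covered index
        for (int k : uncovered) {
            int left = k - 1, right = k + 1;
            while (left >= 0 && !cov[left]) --left;
            while (right < K && !cov[right]) ++right;
            int src;
            if (left < 0) src = right;
            else if (right >= K) src = left;
            else src = (cm[k] - cm[left] <= cm[right] - cm[k]) ? left : right;
            // donors covering src with the same rule as above
            double wsum = 0.0;
            std::vector<int> covm;
            for (int i = 0; i < n; ++i)
                if (s[i] <= src && e[i] >= src) {
                    covm.push_back(i);
                    wsum += (double)(src - s[i]) * (double)(e[i] - src);
                }
            std::vector<double> pr(covm.size());
            for (size_t t = 0; t < covm.size(); ++t) {
                int i = covm[t];
                pr[t] = wsum > 0
                    ? (double)(src - s[i]) * (double)(e[i] - src) / wsum
                    : 1.0 / covm.size();
            }
            for (size_t t = 0; t < covm.size(); ++t)
                acc[refHap[covm[t]]] += pr[t];
            if (perSite) {
                IntegerVector dn(covm.size());
                NumericVector pv(covm.size());
                for (size_t t = 0; t < covm.size(); ++t) {
                    dn[t] = refHap[covm[t]] + 1; pv[t] = pr[t];
                }
                siteDonor[k] = dn; siteProb[k] = pv;
            }
        }
    }

    std::vector<int> nz;
    for (int i = 0; i < N; ++i) if (acc[i] > 0) nz.push_back(i);
    IntegerVector donor(nz.size());
    NumericVector score(nz.size());
    for (size_t t = 0; t < nz.size(); ++t) {
        donor[t] = nz[t] + 1; score[t] = acc[nz[t]];
    }
    List out = List::create(_["donor"] = donor, _["score"] = score);
    if (perSite) { out["siteDonor"] = siteDonor; out["siteProb"] = siteProb; }
    return out;
}
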