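#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Positional Burrows-Wheeler transform machinery.
//
// All haplotype matrices arrive as K x M integer matrices (SNPs in rows,
// haplotypes in columns) so that a haplotype is a contiguous column.
// SNP and haplotype indices are 0-based here; R wrappers shift to 1-based.
//
// Conventions for the per-column arrays at k sites processed:
//   a[i]  sorted haplotype order (by reversed prefix of the first k sites)
//   d[i]  start of the match between a[i] and a[i-1]; d[0] = k (sentinel)

static inline void pbwt_step(const IntegerMatrix &X, int k,
                             std::vector<int> &a, std::vector<int> &d,
                             std::vector<int> &anew, std::vector<int> &dnew) {
    const int M = (int)a.size();
    anew.clear(); dnew.clear();
    static std::vector<int> bv, dbv;
    bv.clear(); dbv.clear();
    int p = k + 1, q = k + 1;
    for (int i = 0; i < M; ++i) {
        if (d[i] > p) p = d[i];
        if (d[i] > q) q = d[i];
        if (X(k, a[i]) == 0) {
            anew.push_back(a[i]); dnew.push_back(p); p = 0;
        } else {
            bv.push_back(a[i]); dbv.push_back(q); q = 0;
        }
    }
    anew.insert(anew.end(), bv.begin(), bv.end());
    dnew.insert(dnew.end(), dbv.begin(), dbv.end());
}

// Build and return the full prefix/divergence arrays (columns 0..K).
// Only intended for panels small enough to materialise; queries below
// sweep and never store more than one column.
// [[Rcpp::export]]
List cpp_build_pbwt(IntegerMatrix X) {
    const int K = X.nrow(), M = X.ncol();
    IntegerMatrix prefix(M, K + 1), diverg(M, K + 1);
    std::vector<int> a(M), d(M, 0), anew, dnew;
    for (int i = 0; i < M; ++i) a[i] = i;
    for (int i = 0; i < M; ++i) { prefix(i, 0) = a[i]; diverg(i, 0) = d[i]; }
    for (int k = 0; k < K; ++k) {
        pbwt_step(X, k, a, d, anew, dnew);
        a.swap(anew); d.swap(dnew);
        for (int i = 0; i < M; ++i) { prefix(i, k + 1) = a[i]; diverg(i, k + 1) = d[i]; }
    }
    return List::create(_["prefix"] = prefix, _["divergence"] = diverg);
}

struct MatchRec { int h1, h2, s, e; };

// Report all maximal matches of SNP length >= L.
// mode 0: cross-panel - haplotypes 0..nRef-1 are the reference, the rest are
//         targets; only (ref, target) pairs are reported (h1 = ref hap).
// mode 1: within panel - all unordered pairs (h1 < h2).
// [[Rcpp::export]]
DataFrame cpp_long_matches(IntegerMatrix X, int nRef, int L, int mode) {
    const int K = X.nrow(), M = X.ncol();
    std::vector<int> a(M), d(M, 0), anew, dnew;
    for (int i = 0; i < M; ++i) a[i] = i;
    std::vector<MatchRec> out;

    for (int k = 0; k <= K; ++k) {
        // scan blocks of haplotypes whose pairwise matches reach back >= L
        int i = 0;
        while (i < M) {
            if (d[i] > k - L) { ++i; continue; }
            int lo = i - 1;           // block is [lo, hi]: d[j] <= k-L for j in (lo, hi]
            int hi = i;
            while (hi + 1 < M && d[hi + 1] <= k - L) ++hi;
            for (int i2 = lo + 1; i2 <= hi; ++i2) {
                int dmax = 0;
                for (int i1 = i2 - 1; i1 >= lo; --i1) {
                    if (d[i1 + 1] > dmax) dmax = d[i1 + 1];
                    if (k - dmax < L) break;
                    int h1 = a[i1], h2 = a[i2];
                    if (k < K && X(k, h1) == X(k, h2)) continue; // extends; reported later
                    bool keep;
                    if (mode == 0) {
                        keep = (h1 < nRef) != (h2 < nRef);
                        if (keep && h1 >= nRef) std::swap(h1, h2);
                    } else {
                        keep = true;
                        if (h1 > h2) std::swap(h1, h2);
                    }
                    if (keep) out.push_back({h1, h2, dmax, k - 1});
                }
            }
            i = hi + 1;
        }
        if (k < K) {
            pbwt_step(X, k, a, d, anew, dnew);
            a.swap(anew); d.swap(dnew);
        }
    }
    const int n = (int)out.size();
    IntegerVector h1(n), h2(n), s(n), e(n);
    for (int t = 0; t < n; ++t) {
        h1[t] = out[t].h1; h2[t] = out[t].h2; s[t] = out[t].s; e[t] = out[t].e;
    }
    return DataFrame::create(_["hap1"] = h1, _["hap2"] = h2, _["s"] = s, _["e"] = e);
}

// Set-maximal matches within a panel: for every haplotype z and position,
// the longest maximal matches to any other panel member covering it.
// A match ending at site e is reported when every neighbour achieving the
// longest match to z disagrees with z at e+1 (or the chromosome ends).
// [[Rcpp::export]]
DataFrame cpp_set_maximal_within(IntegerMatrix X) {
    const int K = X.nrow(), M = X.ncol();
    std::vector<int> a(M), d(M, 0), anew, dnew;
    for (int i = 0; i < M; ++i) a[i] = i;
    std::vector<MatchRec> out;

    for (int k = 0; k <= K; ++k) {
        if (k > 0) {
            for (int i = 0; i < M; ++i) {
                const int dup = (i == 0)     ? k + 1 : d[i];       // match start to predecessor
                const int ddn = (i == M - 1) ? k + 1 : d[i + 1];   // match start to successor
                const int mstart = std::min(dup, ddn);
                if (mstart > k - 1) continue;                      // no non-empty match ends here
                bool ext = false;
                int m = i, n2 = i;
                if (dup <= ddn) {
                    while (m > 0 && d[m] <= dup) {
                        --m;
                        if (k < K && X(k, a[m]) == X(k, a[i])) { ext = true; break; }
                    }
                }
                if (!ext && ddn <= dup) {
                    while (n2 < M - 1 && d[n2 + 1] <= ddn) {
                        ++n2;
                        if (k < K && X(k, a[n2]) == X(k, a[i])) { ext = true; break; }
                    }
                }
                if (ext) continue;
                if (dup <= ddn)
                    for (int j = m; j <= i - 1; ++j) out.push_back({a[i], a[j], dup, k - 1});
                if (ddn <= dup)
                    for (int j = i + 1; j <= n2; ++j) out.push_back({a[i], a[j], ddn, k - 1});
            }
        }
        if (k < K) {
            pbwt_step(X, k, a, d, anew, dnew);
            a.swap(anew); d.swap(dnew);
        }
    }
    const int n = (int)out.size();
    IntegerVector tg(n), rf(n), s(n), e(n);
    for (int t = 0; t < n; ++t) {
        tg[t] = out[t].h1; rf[t] = out[t].h2; s[t] = out[t].s; e[t] = out[t].e;
    }
    return DataFrame::create(_["targetHap"] = tg, _["refHap"] = rf, _["s"] = s, _["e"] = e);
}

// Two-stage selection of at least Q longest matches per SNP, applied to the
// complete list of maximal matches of length >= Lmin for ONE target.
// Stage 1 adds matches in halving length bands [Lq, Lprev) while SNPs remain
// deficient; stage 2 sorts candidates by descending genetic length and keeps
// a match iff it covers a SNP with fewer than Q kept matches.
// Returns 0-based row indices (into the supplied match list) of kept matches.
// [[Rcpp::export]]
IntegerVector cpp_qlongest_select(IntegerVector s, IntegerVector e,
                                  IntegerVector refHap, NumericVector lenCM,
                                  int K, int Q, int Lmin, int L0) {
    const int n = s.size();
    std::vector<int> len(n);
    for (int i = 0; i < n; ++i) len[i] = e[i] - s[i] + 1;

    // coverage by all matches with len >= cut, via difference array
    std::vector<int> cov(K + 1);
    std::vector<char> inS(n, 0), defic(K, 0);
    std::vector<int> covcum(K + 1);
    auto coverage_ge = [&](int cut) {
        std::fill(cov.begin(), cov.end(), 0);
        for (int i = 0; i < n; ++i)
            if (len[i] >= cut) { cov[s[i]]++; cov[e[i] + 1]--; }
        int run = 0;
        for (int k = 0; k < K; ++k) { run += cov[k]; cov[k] = run; }
    };
    auto update_defic = [&]() {   // also builds prefix sums of the deficiency flags
        int nd = 0;
        covcum[0] = 0;
        for (int k = 0; k < K; ++k) {
            defic[k] = (cov[k] < Q);
            nd += defic[k];
            covcum[k + 1] = covcum[k] + defic[k];
        }
        return nd;
    };

    coverage_ge(L0);
    for (int i = 0; i < n; ++i) if (len[i] >= L0) inS[i] = 1;
    int ndef = update_defic();
    int Lprev = L0;
    int Lq = std::max(L0 / 2, Lmin);
    while (ndef > 0 && Lq >= Lmin && Lprev > Lmin) {
        for (int i = 0; i < n; ++i) {
            if (!inS[i] && len[i] >= Lq && len[i] < Lprev &&
                covcum[e[i] + 1] - covcum[s[i]] > 0)
                inS[i] = 1;
        }
        coverage_ge(Lq);
        ndef = update_defic();
        Lprev = Lq;
        if (Lq == Lmin) break;
        Lq = std::max(Lq / 2, Lmin);
    }

    // stage 2: greedy cover by descending genetic length
    std::vector<int> cand;
    for (int i = 0; i < n; ++i) if (inS[i]) cand.push_back(i);
    std::sort(cand.begin(), cand.end(), [&](int x, int y) {
        if (lenCM[x] != lenCM[y]) return lenCM[x] > lenCM[y];
        if (len[x] != len[y]) return len[x] > len[y];
        if (refHap[x] != refHap[y]) return refHap[x] < refHap[y];
        return s[x] < s[y];
    });
    std::vector<int> kept;
    std::vector<int> kcov(K, 0);
    int nfull = 0;
    for (int k = 0; k < K; ++k) if (kcov[k] >= Q) ++nfull; // Q==0 guard
    for (size_t b = 0; b < cand.size(); ++b) {
        if (nfull == K) break;
        const int i = cand[b];
        bool need = false;
        for (int k = s[i]; k <= e[i]; ++k) if (kcov[k] < Q) { need = true; break; }
        if (!need) continue;
        kept.push_back(i);
        for (int k = s[i]; k <= e[i]; ++k) {
            if (++kcov[k] == Q) ++nfull;
        }
    }
    std::sort(kept.begin(), kept.end());
    return IntegerVector(kept.begin(), kept.end());
}
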