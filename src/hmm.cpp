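#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sparse Li & Stephens forward-backward for one target haplotype, mu -> 0.
//
// The per-SNP donor sets s_j come in CSR form (donors, offsets), 0-based over
// the N haplotypes of the donor pool. Every SNP must have a non-empty donor
// set (imputation guarantees this upstream).
//
// Normalised recursions, 0-based SNPs j = 0..K-1, gaps[j] in Morgans between
// SNPs j and j+1, rho_j = exp(-lambda * gaps[j]), rhot_j = (1 - rho_j)/N:
//   forward : f*_ij = rho_{j-1} f_{i,j-1} + rhot_{j-1} for i in s_j,
//             F_j = sum f*, f_ij = f*_ij / F_j, with F_0 = |s_0| / N.
//   backward: b at the last SNP is 1/N for everyone; stepping left,
//             b*_ij = rho_j b_{i,j+1} + rhot_j ctil for i in s_{j+1}, default
//             rhot_j ctil otherwise, ctil = sum of b over s_{j+1};
//             B_j = sum over s_{j+1} of b* + (N - n_{j+1}) * default.
// Posterior at j is proportional to f_ij b_ij on s_j.  Chunk lengths and
// counts use the log-accumulated F/B normalisers:
//   wl_j = exp(logFcum_j + logBcum_j - logPrD)  (logPrD = logFcum_{K-1}),
//   lhat_i += g_j/2 * (wl_j f_ij b_ij + wl_{j+1} f_{i,j+1} b_{i,j+1}),
//   chat_i  = wl_0 f_i0 b_i0
//           + sum_j [ wl_{j+1} f b (j+1) - ar_j f_ij b_{i,j+1} m_{i,j+1} rho_j ],
//   ar_j = exp(logFcum_j + logBcum_{j+1} - logPrD).
//
// [[Rcpp::export]]
List cpp_sparse_paint(IntegerVector donors, IntegerVector offsets,
                      int N, NumericVector gaps, double lambda,
                      IntegerVector donorPop, int npop, bool wantProbs) {
    const int K = offsets.size() - 1;
    const int nd = donors.size();
    if (K < 1) stop("empty chromosome");
    const double GMIN = 1e-12;  // zero map gaps clamped so new donors stay reachable

    std::vector<double> rho(K > 1 ? K - 1 : 0), rhot(K > 1 ? K - 1 : 0);
    for (int j = 0; j + 1 < K; ++j) {
        double g = gaps[j] > GMIN ? gaps[j] : GMIN;
        rho[j] = std::exp(-lambda * g);
        rhot[j] = (1.0 - rho[j]) / N;
    }

    // ---- forward ----
    std::vector<double> fv(nd);           // normalised forward, aligned to CSR
    std::vector<double> logFcum(K);
    std::vector<int> mark(N, -1), pos(N, 0);
    {
        int o0 = offsets[0], o1 = offsets[1];
        int n0 = o1 - o0;
        if (n0 == 0) stop("SNP 1 has no donors");
        double F = (double)n0 / N;
        for (int t = o0; t < o1; ++t) {
            fv[t] = 1.0 / n0;
            mark[donors[t]] = 0; pos[donors[t]] = t;
        }
        logFcum[0] = std::log(F);
    }
    for (int j = 1; j < K; ++j) {
        const int oa = offsets[j], ob = offsets[j + 1];
        if (ob == oa) stop("SNP %d has no donors", j + 1);
        double F = 0.0;
        for (int t = oa; t < ob; ++t) {
            const int i = donors[t];
            double f = rhot[j - 1];
            if (mark[i] == j - 1) f += rho[j - 1] * fv[pos[i]];
            fv[t] = f; F += f;
        }
        const double inv = 1.0 / F;
        for (int t = oa; t < ob; ++t) {
            const int i = donors[t];
            fv[t] *= inv;
            mark[i] = j; pos[i] = t;
        }
        logFcum[j] = logFcum[j - 1] + std::log(F);
    }
    const double logPrD = logFcum[K - 1];

    // ---- backward ----
    std::vector<double> bv(nd);           // b at SNP j for donors of column j
    std::vector<double> bdef(K);          // default value of b_j off s_{j+1}
    std::vector<double> logBcum(K);
    std::fill(mark.begin(), mark.end(), -1);
    {
        const int j = K - 1;
        const double val = 1.0 / N;
        bdef[j] = val;
        for (int t = offsets[j]; t < offsets[j + 1]; ++t) {
            bv[t] = val; mark[donors[t]] = j; pos[donors[t]] = t;
        }
        logBcum[j] = std::log((double)N);
    }
    std::vector<double> sc(N);            // scratch: normalised b*_ij keyed by donor
    for (int j = K - 2; j >= 0; --j) {
        const int oa1 = offsets[j + 1], ob1 = offsets[j + 2]; // s_{j+1}
        const int n1 = ob1 - oa1;
        double ctil = 0.0;
        for (int t = oa1; t < ob1; ++t) ctil += bv[t];
        const double defstar = rhot[j] * ctil;
        double B = (double)(N - n1) * defstar;
        for (int t = oa1; t < ob1; ++t) B += rho[j] * bv[t] + defstar;
        const double invB = 1.0 / B;
        const double bdefj = defstar * invB;
        // matched values of b_j live on s_{j+1}; column j+1's slice of bv holds
        // b_{i,j+1} and is left untouched (the chunk-count cross term reads it)
        for (int t = oa1; t < ob1; ++t) {
            const int i = donors[t];
            sc[i] = (rho[j] * bv[t] + defstar) * invB;
            mark[i] = j;
        }
        for (int t = offsets[j]; t < offsets[j + 1]; ++t) {
            const int i = donors[t];
            bv[t] = (mark[i] == j) ? sc[i] : bdefj;
        }
        bdef[j] = bdefj;
        logBcum[j] = logBcum[j + 1] + std::log(B);
    }

    // ---- posterior, chunk lengths, chunk counts ----
    NumericMatrix popprob(wantProbs ? npop : 0, wantProbs ? K : 0);
    NumericVector lhat(N), chat(N);
    std::vector<double> wl(K);
    for (int j = 0; j < K; ++j) wl[j] = std::exp(logFcum[j] + logBcum[j] - logPrD);

    for (int j = 0; j < K; ++j) {
        const int oa = offsets[j], ob = offsets[j + 1];
        if (wantProbs) {
            double tot = 0.0;
            for (int t = oa; t < ob; ++t) tot += fv[t] * bv[t];
            const double inv = tot > 0 ? 1.0 / tot : 0.0;
            for (int t = oa; t < ob; ++t)
                popprob(donorPop[donors[t]], j) += fv[t] * bv[t] * inv;
        }
    }
    // lhat
    for (int j = 0; j + 1 < K; ++j) {
        const double g = gaps[j];
        if (g <= 0) continue;
        const double cl = 0.5 * g * wl[j], cr = 0.5 * g * wl[j + 1];
        for (int t = offsets[j]; t < offsets[j + 1]; ++t)
            lhat[donors[t]] += cl * fv[t] * bv[t];
        for (int t = offsets[j + 1]; t < offsets[j + 2]; ++t)
            lhat[donors[t]] += cr * fv[t] * bv[t];
    }
    // chat
    std::fill(mark.begin(), mark.end(), -1);
    for (int t = offsets[0]; t < offsets[1]; ++t)
        chat[donors[t]] += wl[0] * fv[t] * bv[t];
    for (int j = 0; j + 1 < K; ++j) {
        const double ar = std::exp(logFcum[j] + logBcum[j + 1] - logPrD);
        const int oa1 = offsets[j + 1], ob1 = offsets[j + 2];
        for (int t = oa1; t < ob1; ++t) {
            const int i = donors[t];
            chat[i] += wl[j + 1] * fv[t] * bv[t];
            mark[i] = j + 1; pos[i] = t;   // membership of s_{j+1}
        }
        // cross term over i in s_j (f side) that are also in s_{j+1}
        for (int t = offsets[j]; t < offsets[j + 1]; ++t) {
            const int i = donors[t];
            if (mark[i] == j + 1)
                chat[i] -= ar * fv[t] * bv[pos[i]] * rho[j];
        }
    }

    return List::create(_["popprob"] = popprob, _["lhat"] = lhat,
                        _["chat"] = chat, _["loglik"] = logPrD,
                        _["logFcum"] = NumericVector(logFcum.begin(), logFcum.end()),
                        _["logBcum"] = NumericVector(logBcum.begin(), logBcum.end()),
                        _["fvals"] = NumericVector(fv.begin(), fv.end()),
                        _["bvals"] = NumericVector(bv.begin(), bv.end()));
}

// Convert a per-target match table into CSR per-SNP donor sets, deduplicated.
// s, e are 0-based inclusive; donor 0-based pool indices.
// [[Rcpp::export]]
List cpp_matches_to_csr(IntegerVector s, IntegerVector e, IntegerVector donor,
                        int K) {
    const int n = s.size();
    std::vector<int> cnt(K + 1, 0);
    for (int i = 0; i < n; ++i)
        for (int k = s[i]; k <= e[i]; ++k) ++cnt[k + 1];
    for (int k = 0; k < K; ++k) cnt[k + 1] += cnt[k];
    std::vector<int> fill(cnt.begin(), cnt.end() - 1);
    std::vector<int> dn(cnt[K]);
    for (int i = 0; i < n; ++i)
        for (int k = s[i]; k <= e[i]; ++k) dn[fill[k]++] = donor[i];
    // dedup per column
    std::vector<int> offs(K + 1, 0), out;
    out.reserve(dn.size());
    for (int k = 0; k < K; ++k) {
        int a = cnt[k], b = cnt[k + 1];
        std::sort(dn.begin() + a, dn.begin() + b);
        int last = -1;
        for (int t = a; t < b; ++t)
            if (dn[t] != last) { out.push_back(dn[t]); last = dn[t]; }
        offs[k + 1] = (int)out.size();
    }
    return List::create(_["donors"] = IntegerVector(out.begin(), out.end()),
                        _["offsets"] = IntegerVector(offs.begin(), offs.end()));
}
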