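#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fisher-Yates permutation of 0..n-1 using R's RNG so that set.seed()
// upstream makes every null model reproducible.
static void fy_perm(std::vector<int>& p) {
    const int n = (int)p.size();
    for (int i = 0; i < n; ++i) p[i] = i;
    for (int i = n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(p[i], p[j]);
    }
}

// Pairwise beta-MNTD for all samples given a (possibly label-permuted)
// cophenetic matrix. W holds per-sample taxon weights (relative abundances
// for the weighted statistic, 1/richness incidences for the unweighted one);
// pres holds the indices of taxa with W > 0 per sample.
//
// Mtmp(a, l) = min over j in pres[l] of D(a, perm[j]);
// A(k, l)    = sum_i W(k, i) * Mtmp(perm[i], l);
// B          = 0.5 * (A + A').
static void beta_mntd_core(const NumericMatrix& D, const NumericMatrix& W,
                           const std::vector< std::vector<int> >& pres,
                           const std::vector<int>& perm,
                           NumericMatrix& B, std::vector<double>& Mtmp,
                           std::vector<double>& A) {
    const int S = W.nrow(), N = W.ncol();
    for (int l = 0; l < S; ++l) {
        double* Mcol = &Mtmp[(size_t)l * N];
        for (int a = 0; a < N; ++a) Mcol[a] = R_PosInf;
        for (size_t jj = 0; jj < pres[l].size(); ++jj) {
            const double* Dcol = &D[(size_t)perm[pres[l][jj]] * N];
            for (int a = 0; a < N; ++a) {
                if (Dcol[a] < Mcol[a]) Mcol[a] = Dcol[a];
            }
        }
    }
    std::fill(A.begin(), A.end(), 0.0);
    for (int l = 0; l < S; ++l) {
        double* Acol = &A[(size_t)l * S];
        const double* Mcol = &Mtmp[(size_t)l * N];
        for (int i = 0; i < N; ++i) {
            const double m = Mcol[perm[i]];
            if (m == 0.0) continue;
            const double* Wcol = &W[(size_t)i * S];
            for (int k = 0; k < S; ++k) Acol[k] += Wcol[k] * m;
        }
    }
    for (int l = 0; l < S; ++l)
        for (int k = 0; k < S; ++k)
            B(k, l) = 0.5 * (A[(size_t)l * S + k] + A[(size_t)k * S + l]);
}

static std::vector< std::vector<int> > presence_lists(const NumericMatrix& W) {
    const int S = W.nrow(), N = W.ncol();
    std::vector< std::vector<int> > pres(S);
    for (int i = 0; i < N; ++i)
        for (int k = 0; k < S; ++k)
            if (W(k, i) > 0) pres[k].push_back(i);
    return pres;
}

// [[Rcpp::export]]
NumericMatrix cpp_beta_mntd(NumericMatrix D, NumericMatrix W) {
    const int S = W.nrow(), N = W.ncol();
    std::vector< std::vector<int> > pres = presence_lists(W);
    std::vector<int> id(N);
    for (int i = 0; i < N; ++i) id[i] = i;
    NumericMatrix B(S, S);
    std::vector<double> Mtmp((size_t)N * S), A((size_t)S * S);
    beta_mntd_core(D, W, pres, id, B, Mtmp, A);
    return B;
}

// [[Rcpp::export]]
List cpp_beta_nti(NumericMatrix D, NumericMatrix W, int n_null) {
    const int S = W.nrow(), N = W.ncol();
    std::vector< std::vector<int> > pres = presence_lists(W);
    std::vector<int> perm(N);
    for (int i = 0; i < N; ++i) perm[i] = i;
    NumericMatrix obs(S, S), Bn(S, S), msum(S, S), msq(S, S);
    std::vector<double> Mtmp((size_t)N * S), A((size_t)S * S);
    beta_mntd_core(D, W, pres, perm, obs, Mtmp, A);
    for (int b = 0; b < n_null; ++b) {
        fy_perm(perm);
        beta_mntd_core(D, W, pres, perm, Bn, Mtmp, A);
        for (int l = 0; l < S; ++l)
            for (int k = 0; k < S; ++k) {
                msum(k, l) += Bn(k, l);
                msq(k, l) += Bn(k, l) * Bn(k, l);
            }
        if (b % 64 == 0) Rcpp::checkUserInterrupt();
    }
    NumericMatrix nmean(S, S), nsd(S, S);
    for (int l = 0; l < S; ++l)
        for (int k = 0; k < S; ++k) {
            nmean(k, l) = msum(k, l) / n_null;
            double v = n_null > 1 ?
                (msq(k, l) - msum(k, l) * msum(k, l) / n_null) / (n_null - 1) : 0.0;
            nsd(k, l) = v > 0 ? std::sqrt(v) : 0.0;
        }
    return List::create(_["obs"] = obs, _["null_mean"] = nmean,
                        _["null_sd"] = nsd);
}

// Per-sample MNTD (nearest neighbour excludes self) under an optional label
// permutation of the cophenetic matrix.
static double mntd_one(const NumericMatrix& D, const std::vector<int>& pres,
                       const std::vector<double>& w,
                       const std::vector<int>& perm) {
    const size_t r = pres.size();
    if (r < 2) return NA_REAL;
    double tot = 0.0;
    for (size_t a = 0; a < r; ++a) {
        const int ia = perm[pres[a]];
        double nd = R_PosInf;
        for (size_t b = 0; b < r; ++b) {
            if (a == b) continue;
            const double v = D(ia, perm[pres[b]]);
            if (v < nd) nd = v;
        }
        tot += w[a] * nd;
    }
    return tot;
}

// [[Rcpp::export]]
List cpp_ses_mntd(NumericMatrix D, NumericMatrix W, int n_null) {
    const int S = W.nrow(), N = W.ncol();
    std::vector< std::vector<int> > pres = presence_lists(W);
    std::vector< std::vector<double> > wts(S);
    for (int k = 0; k < S; ++k)
        for (size_t a = 0; a < pres[k].size(); ++a)
            wts[k].push_back(W(k, pres[k][a]));
    std::vector<int> perm(N);
    for (int i = 0; i < N; ++i) perm[i] = i;
    NumericVector obs(S), nmean(S), nsd(S);
    for (int k = 0; k < S; ++k) obs[k] = mntd_one(D, pres[k], wts[k], perm);
    std::vector<double> msum(S, 0.0), msq(S, 0.0);
    for (int b = 0; b < n_null; ++b) {
        fy_perm(perm);
        for (int k = 0; k < S; ++k) {
            const double v = mntd_one(D, pres[k], wts[k], perm);
            msum[k] += v;
            msq[k] += v * v;
        }
        if (b % 64 == 0) Rcpp::checkUserInterrupt();
    }
    for (int k = 0; k < S; ++k) {
        nmean[k] = msum[k] / n_null;
        double v = n_null > 1 ?
            (msq[k] - msum[k] * msum[k] / n_null) / (n_null - 1) : 0.0;
        nsd[k] = v > 0 ? std::sqrt(v) : 0.0;
    }
    return List::create(_["obs"] = obs, _["null_mean"] = nmean,
                        _["null_sd"] = nsd);
}

// Weighted sampling of r items without replacement, probability proportional
// to w at each successive draw. Implemented by the exponential-key trick
// (keys u^(1/w), take the r largest), which has the same distribution as the
// sequential scheme and costs O(N) per community.
static void weighted_draw(const NumericVector& w, int r, std::vector<int>& out,
                          std::vector< std::pair<double,int> >& keys) {
    keys.clear();
    const int N = w.size();
    // log(u)/w is a monotone transform of u^(1/w); only set membership of
    // the top r matters, so nth_element suffices.
    for (int i = 0; i < N; ++i) {
        if (w[i] > 0) keys.push_back(std::make_pair(std::log(unif_rand()) / w[i], i));
    }
    std::nth_element(keys.begin(), keys.begin() + (r - 1), keys.end(),
                     [](const std::pair<double,int>& a, const std::pair<double,int>& b) {
                         return a.first > b.first;
                     });
    out.clear();
    for (int a = 0; a < r; ++a) out.push_back(keys[a].second);
}

// Build one Raup-Crick null community: r taxa drawn by occupancy, each
// seeded with one read, the remaining reads allocated multinomially by
// metacommunity relative abundance.
static void rc_null_comm(const NumericVector& occ, const NumericVector& relab,
                         int r, int reads, std::vector<int>& taxa,
                         std::vector<double>& cnt,
                         std::vector< std::pair<double,int> >& keys) {
    weighted_draw(occ, r, taxa, keys);
    cnt.assign(taxa.size(), 1.0);
    int m = reads - r;
    if (m > 0) {
        double rest = 0.0;
        for (size_t a = 0; a < taxa.size(); ++a) rest += relab[taxa[a]];
        for (size_t a = 0; a + 1 < taxa.size() && m > 0; ++a) {
            const double p = relab[taxa[a]];
            if (rest <= 0) break;
            const int x = (int)R::rbinom((double)m, std::min(1.0, p / rest));
            cnt[a] += x;
            m -= x;
            rest -= p;
        }
        if (m > 0) cnt[taxa.size() - 1] += m;
    }
}

// Bray-Curtis between two sparse relative-abundance communities using a
// dense scratch vector (reset via the touched-index list).
static double bc_sparse(const std::vector<int>& t1, const std::vector<double>& c1,
                        const std::vector<int>& t2, const std::vector<double>& c2,
                        std::vector<double>& dense) {
    double n1 = 0, n2 = 0;
    for (double v : c1) n1 += v;
    for (double v : c2) n2 += v;
    for (size_t a = 0; a < t1.size(); ++a) dense[t1[a]] = c1[a] / n1;
    double shared = 0.0;
    for (size_t a = 0; a < t2.size(); ++a) {
        const double p2 = c2[a] / n2;
        const double p1 = dense[t2[a]];
        shared += (p1 < p2 ? p1 : p2);
    }
    for (size_t a = 0; a < t1.size(); ++a) dense[t1[a]] = 0.0;
    return 1.0 - shared;
}

// [[Rcpp::export]]
NumericVector cpp_rc_bray(IntegerMatrix C, NumericVector occ, NumericVector relab,
                          IntegerMatrix pairs, int n_null, double tie_tol) {
    const int S = C.nrow(), N = C.ncol(), P = pairs.nrow();
    std::vector< std::vector<int> > pres(S);
    std::vector<int> reads(S, 0);
    for (int i = 0; i < N; ++i)
        for (int k = 0; k < S; ++k)
            if (C(k, i) > 0) { pres[k].push_back(i); reads[k] += C(k, i); }
    std::vector<double> dense(N, 0.0);
    std::vector< std::pair<double,int> > keys;
    std::vector<int> t1, t2;
    std::vector<double> c1, c2;
    NumericVector rc(P);
    for (int p = 0; p < P; ++p) {
        const int k = pairs(p, 0) - 1, l = pairs(p, 1) - 1;
        // observed BC on counts
        std::vector<double> ok, ol;
        for (int idx : pres[k]) ok.push_back((double)C(k, idx));
        for (int idx : pres[l]) ol.push_back((double)C(l, idx));
        const double bc_obs = bc_sparse(pres[k], ok, pres[l], ol, dense);
        double below = 0.0, equal = 0.0;
        for (int b = 0; b < n_null; ++b) {
            rc_null_comm(occ, relab, (int)pres[k].size(), reads[k], t1, c1, keys);
            rc_null_comm(occ, relab, (int)pres[l].size(), reads[l], t2, c2, keys);
            const double bc = bc_sparse(t1, c1, t2, c2, dense);
            if (bc < bc_obs - tie_tol) below += 1.0;
            else if (bc <= bc_obs + tie_tol) equal += 1.0;
        }
        rc[p] = 2.0 * ((below + 0.5 * equal) / n_null - 0.5);
        Rcpp::checkUserInterrupt();
    }
    return rc;
}
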