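#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Circular binary segmentation kernel.
//
// For a series x[0..n) treated as circular, the candidate splits are arcs
// (i, j] with 0 <= i < j <= n.  The test statistic is the two-sample
// pooled-variance t between the arc and its complement.  A split is accepted
// when the permutation p-value of the maximal |t| falls below alpha; the arc
// endpoints become breakpoints and the search recurses on the resulting
// linear pieces.  Ties in |t| break to the leftmost (i, then j) candidate.

namespace {

struct ArcStat {
    double t;      // |t|; +Inf when both groups are internally constant
    int i, j;      // arc is positions (i, j], breakpoints at i and j
};

const double kVarEps = 1e-12;

// Maximal arc statistic under min-width constraints: every resulting linear
// piece (left [0,i), mid (i,j], right (j,n)) must have >= minw elements.
ArcStat max_arc_t(const std::vector<double>& x, int minw) {
    const int n = static_cast<int>(x.size());
    ArcStat best{0.0, -1, -1};
    if (n < 2 * minw) return best;

    std::vector<double> S(n + 1, 0.0), SS(n + 1, 0.0);
    for (int k = 0; k < n; ++k) {
        S[k + 1] = S[k] + x[k];
        SS[k + 1] = SS[k] + x[k] * x[k];
    }
    const double tot = S[n], totss = SS[n];

    for (int i = 0; i <= n - minw; ++i) {
        if (i > 0 && i < minw) continue;          // left piece too small
        for (int j = i + minw; j <= n; ++j) {
            if (j < n && n - j < minw) continue;  // right piece too small
            if (i == 0 && j == n) continue;       // empty complement
            const int L = j - i, M = n - L;
            const double sum1 = S[j] - S[i];
            const double sum2 = tot - sum1;
            const double m1 = sum1 / L, m2 = sum2 / M;
            double ss1 = (SS[j] - SS[i]) - L * m1 * m1;
            double ss2 = (totss - (SS[j] - SS[i])) - M * m2 * m2;
            if (ss1 < 0) ss1 = 0;
            if (ss2 < 0) ss2 = 0;
            double t;
            const double df = n - 2;
            const double pooled = df > 0 ? (ss1 + ss2) / df : 0.0;
            if (pooled <= kVarEps) {
                t = (std::fabs(m1 - m2) <= 1e-9) ? 0.0 : R_PosInf;
            } else {
                t = std::fabs(m1 - m2) / std::sqrt(pooled * (1.0 / L + 1.0 / M));
            }
            if (t > best.t) { best.t = t; best.i = i; best.j = j; }
        }
    }
    return best;
}

// Permutation p-value for the observed maximal statistic, with early exit
// once the exceedance count guarantees p >= alpha.
double perm_pvalue(const std::vector<double>& x, int minw, double obs,
                   int nperm, double alpha, std::mt19937_64& rng) {
    if (!(obs > 0)) return 1.0;
    std::vector<double> y(x);
    const int n = static_cast<int>(y.size());
    const int stop_at = static_cast<int>(std::ceil(alpha * nperm));
    int exceed = 0;
    for (int b = 0; b < nperm; ++b) {
        for (int k = n - 1; k > 0; --k) {   // Fisher-Yates, deterministic given seed
            int r = static_cast<int>(rng() % static_cast<uint64_t>(k + 1));
            std::swap(y[k], y[r]);
        }
        ArcStat s = max_arc_t(y, minw);
        bool ge;
        if (obs == R_PosInf) ge = (s.t == R_PosInf);
        else ge = (s.t >= obs * (1.0 - 1e-12));
        if (ge && ++exceed >= stop_at) return static_cast<double>(stop_at) / nperm;
    }
    return static_cast<double>(exceed) / nperm;
}

void segment_recurse(const std::vector<double>& x, int lo, int hi,
                     double alpha, int nperm, int minw,
                     std::mt19937_64& rng, std::vector<int>& breaks) {
    const int n = hi - lo;
    if (n < 2 * minw) return;
    std::vector<double> sub(x.begin() + lo, x.begin() + hi);
    ArcStat s = max_arc_t(sub, minw);
    if (!(s.t > 0)) return;
    // A perfectly separating arc (both sides exactly constant) is accepted
    // without a permutation test: it only arises in the noise-free limit,
    // where the split is certain.
    if (s.t != R_PosInf) {
        double p = perm_pvalue(sub, minw, s.t, nperm, alpha, rng);
        if (p >= alpha) return;
    }
    const int i = s.i, j = s.j;
    if (i > 0) breaks.push_back(lo + i);
    if (j < n) breaks.push_back(lo + j);
    if (i > 0) segment_recurse(x, lo, lo + i, alpha, nperm, minw, rng, breaks);
    segment_recurse(x, lo + i, lo + j, alpha, nperm, minw, rng, breaks);
    if (j < n) segment_recurse(x, lo + j, hi, alpha, nperm, minw, rng, breaks);
}

} // namespace

// [[Rcpp::export]]
List cpp_max_arc_t(NumericVector x, int min_width) {
    std::vector<double> v(x.begin(), x.end());
    ArcStat s = max_arc_t(v, min_width);
    return List::create(_["t"] = s.t, _["i"] = s.i, _["j"] = s.j);
}

// [[Rcpp::export]]
IntegerVector cpp_cbs_breakpoints(NumericVector x, double alpha, int n_perm,
                                  int min_bins, double seed) {
    std::vector<double> v(x.begin(), x.end());
    std::mt19937_64 rng(static_cast<uint64_t>(seed));
    std::vector<int> breaks;
    segment_recurse(v, 0, static_cast<int>(v.size()), alpha, n_perm, min_bins,
                    rng, breaks);
    std::sort(breaks.begin(), breaks.end());
    breaks.erase(std::unique(breaks.begin(), breaks.end()), breaks.end());
    return wrap(breaks);
}
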