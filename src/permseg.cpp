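#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

// Permutation null for the best-split t-statistic of one interval.
//
// For each of nPerm permutations of x, the maximum absolute two-sample
// t-statistic over all candidate split points (leaving >= minBins bins on
// each side) is compared with the observed statistic. Scanning stops as
// soon as the exceedance count reaches alpha * nPerm, at which point the
// split is already rejected; the decision is identical to the full scan.
//
// Permutations use an explicit Fisher-Yates shuffle driven by a local
// 64-bit splitmix/xorshift generator seeded from `seed`, so results are
// reproducible across platforms and independent of R's RNG state.

namespace {

struct Rng64 {
  uint64_t s;
  explicit Rng64(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, bound)
  uint64_t below(uint64_t bound) { return next() % bound; }
};

double maxAbsT(const std::vector<double>& x, int minBins, double tot,
               double tot2) {
  const int n = static_cast<int>(x.size());
  double s1 = 0.0, s2 = 0.0, best = 0.0;
  for (int i = 0; i < n - minBins; ++i) {
    s1 += x[i];
    s2 += x[i] * x[i];
    const int nl = i + 1;
    if (nl < minBins) continue;
    const int nr = n - nl;
    const double mL = s1 / nl;
    const double mR = (tot - s1) / nr;
    double sp2 = (s2 - nl * mL * mL) + ((tot2 - s2) - nr * mR * mR);
    if (sp2 < 0.0) sp2 = 0.0;
    sp2 /= (n - 2);
    const double den = std::sqrt(sp2 * (1.0 / nl + 1.0 / nr));
    const double d = std::fabs(mL - mR);
    double t;
    if (den > 0.0) {
      t = d / den;
    } else {
      t = (d > 0.0) ? R_PosInf : 0.0;
    }
    if (t > best) best = t;
  }
  return best;
}

}  // namespace

namespace {

// Max |t| of the two-changepoint (inside-vs-outside) statistic over all
// interior windows of length in [minBins, cap], with at least minBins
// bins outside. Optionally reports the best window.
double maxBumpT(const std::vector<double>& x, int minBins, int cap,
                double tot, double tot2, int* bestA, int* bestB) {
  const int n = static_cast<int>(x.size());
  double best = -1.0;
  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    S2[i + 1] = S2[i] + x[i] * x[i];
  }
  for (int a = 1; a <= n; ++a) {
    const int bmax = std::min(n, a + cap - 1);
    for (int b = a + minBins - 1; b <= bmax; ++b) {
      const int nin = b - a + 1;
      const int nout = n - nin;
      if (nout < minBins) continue;
      const double sIn = S[b] - S[a - 1];
      const double s2In = S2[b] - S2[a - 1];
      const double mIn = sIn / nin;
      const double mOut = (tot - sIn) / nout;
      double sp2 = (s2In - nin * mIn * mIn) +
                   ((tot2 - s2In) - nout * mOut * mOut);
      if (sp2 < 0.0) sp2 = 0.0;
      sp2 /= (n - 2);
      const double den = std::sqrt(sp2 * (1.0 / nin + 1.0 / nout));
      const double d = std::fabs(mIn - mOut);
      double t;
      if (den > 0.0) {
        t = d / den;
      } else {
        t = (d > 0.0) ? R_PosInf : 0.0;
      }
      if (t > best) {
        best = t;
        if (bestA) { *bestA = a; *bestB = b; }
      }
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".bestBumpSplit")]]
Rcpp::List bestBumpSplit(Rcpp::NumericVector x, int minBins, int cap) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  double tot = 0.0, tot2 = 0.0;
  for (int i = 0; i < n; ++i) {
    tot += v[i];
    tot2 += v[i] * v[i];
  }
  int a = -1, b = -1;
  const double stat = maxBumpT(v, minBins, cap, tot, tot2, &a, &b);
  return Rcpp::List::create(Rcpp::Named("stat") = stat,
                            Rcpp::Named("a") = a, Rcpp::Named("b") = b);
}

// [[Rcpp::export(name = ".permBumpAccept")]]
bool permBumpAccept(Rcpp::NumericVector x, double obs, int minBins,
                    int cap, double alpha, int nPerm, double seed) {
  const int n = x.size();
  if (n < minBins * 2 || !(obs > 0.0)) return false;
  std::vector<double> v(x.begin(), x.end());
  double tot = 0.0, tot2 = 0.0;
  for (int i = 0; i < n; ++i) {
    tot += v[i];
    tot2 += v[i] * v[i];
  }
  const double need = alpha * static_cast<double>(nPerm);
  double count = 0.0;
  Rng64 rng(static_cast<uint64_t>(seed));
  for (int p = 0; p < nPerm; ++p) {
    for (int j = n - 1; j > 0; --j) {
      const int k = static_cast<int>(rng.below(j + 1));
      std::swap(v[j], v[k]);
    }
    if (maxBumpT(v, minBins, cap, tot, tot2, nullptr, nullptr) >= obs) {
      count += 1.0;
      if (count >= need) return false;
    }
  }
  return count < need;
}

// [[Rcpp::export(name = ".permSplitAccept")]]
bool permSplitAccept(Rcpp::NumericVector x, double obs, int minBins,
                     double alpha, int nPerm, double seed) {
  const int n = x.size();
  if (n < 2 * minBins) return false;
  if (!(obs > 0.0)) return false;
  std::vector<double> v(x.begin(), x.end());
  double tot = 0.0, tot2 = 0.0;
  for (int i = 0; i < n; ++i) {
    tot += v[i];
    tot2 += v[i] * v[i];
  }
  const double need = alpha * static_cast<double>(nPerm);
  double count = 0.0;
  Rng64 rng(static_cast<uint64_t>(seed));
  for (int p = 0; p < nPerm; ++p) {
    for (int j = n - 1; j > 0; --j) {
      const int k = static_cast<int>(rng.below(j + 1));
      std::swap(v[j], v[k]);
    }
    if (maxAbsT(v, minBins, tot, tot2) >= obs) {
      count += 1.0;
      if (count >= need) return false;
    }
  }
  return count < need;
}
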