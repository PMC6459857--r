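#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Multi-tau photon-mode correlator (weighted pair counting).
//
// Lag grid: cascade 0 covers lags 1..2m ticks of width delta0; every further
// cascade doubles the tick width and covers lags m+1..2m.  Photon lists are
// coarsened (duplicate ticks merged, weights summed) at the start of each
// cascade; because merged ticks are distinct integers, at most 2m partners
// can sit inside the lag window of any photon, so the pair search is O(n)
// per cascade.
//
// Pairs are counted forward in time (weight1 at the earlier photon, weight2
// at the later), so cross-correlations of distinct filters are ordered.
// Normalisation: for uncorrelated Poisson streams the expected weighted pair
// count at lag tau in a bin of width delta is W1*W2*delta*(T-tau)/T^2, so
// dividing by it yields G = 1 flat.

namespace {

void coarsen(std::vector<double>& tick, std::vector<double>& w1,
             std::vector<double>& w2) {
  size_t j = 0;
  for (size_t i = 0; i < tick.size(); ++i) {
    double t2 = std::floor(tick[i] / 2.0);
    if (j > 0 && tick[j - 1] == t2) {
      w1[j - 1] += w1[i]; w2[j - 1] += w2[i];
    } else {
      tick[j] = t2; w1[j] = w1[i]; w2[j] = w2[i]; ++j;
    }
  }
  tick.resize(j); w1.resize(j); w2.resize(j);
}

} // namespace

// [[Rcpp::export]]
List correlate_cpp(NumericVector t, NumericVector weight1,
                   NumericVector weight2, double T_total,
                   double delta0, int m, int n_casc) {
  const int n0 = t.size();
  std::vector<double> tick, w1, w2;
  tick.reserve(n0); w1.reserve(n0); w2.reserve(n0);
  for (int i = 0; i < n0; ++i) {
    double tk = std::floor(t[i] / delta0);
    if (!tick.empty() && tick.back() == tk) {
      w1.back() += weight1[i]; w2.back() += weight2[i];
    } else {
      tick.push_back(tk); w1.push_back(weight1[i]); w2.push_back(weight2[i]);
    }
  }

  double W1 = 0, W2 = 0;
  for (int i = 0; i < n0; ++i) { W1 += weight1[i]; W2 += weight2[i]; }

  std::vector<double> lags, G;
  double delta = delta0;
  for (int c = 0; c < n_casc; ++c) {
    int lag_lo = (c == 0) ? 1 : m + 1;
    int lag_hi = 2 * m;            // inclusive
    int nlag = lag_hi - lag_lo + 1;
    std::vector<double> S(nlag, 0.0);
    const size_t n = tick.size();
    for (size_t i = 0; i < n; ++i) {
      for (size_t j = i + 1; j < n; ++j) {
        double d = tick[j] - tick[i];
        if (d > lag_hi) break;
        if (d < lag_lo) continue;
        S[(int)d - lag_lo] += w1[i] * w2[j];
      }
    }
    for (int l = 0; l < nlag; ++l) {
      double tau = (lag_lo + l) * delta;
      if (tau >= T_total) continue;
      double expect = W1 * W2 * delta * (T_total - tau) / (T_total * T_total);
      lags.push_back(tau);
      G.push_back(expect > 0 ? S[l] / expect : NA_REAL);
    }
    coarsen(tick, w1, w2);
    delta *= 2.0;
  }
  return List::create(_["lag"] = wrap(lags), _["G"] = wrap(G));
}
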