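#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shot-noise PDA forward model.
//
// For every window photon total N the probability of observing s "success"
// photons (red for FRET, parallel for anisotropy) is built by mixing over
// conformational states, integrating each state's Gaussian observable
// distribution on quadrature nodes, convolving with binomial counting
// statistics, and convolving with Poisson background in both channels.
// The observable value implied by (s, N) is then histogrammed on the
// supplied bin edges using the same estimator the burst analysis applies
// to measured counts.

namespace {

// binomial pmf on 0..F started at the mode and recurred outward; entries
// below `tiny` are dropped (they cannot move histogram mass noticeably)
void binom_pmf(int F, double p, std::vector<double>& pmf, int& lo, int& hi) {
  const double tiny = 1e-13;
  pmf.assign(F + 1, 0.0);
  if (F == 0) { pmf[0] = 1.0; lo = hi = 0; return; }
  if (p <= 0) { pmf[0] = 1.0; lo = hi = 0; return; }
  if (p >= 1) { pmf[F] = 1.0; lo = hi = F; return; }
  int m0 = (int)std::floor((F + 1.0) * p);
  if (m0 > F) m0 = F;
  double pm = R::dbinom(m0, F, p, 0);
  pmf[m0] = pm;
  const double odds = p / (1.0 - p);
  hi = m0;
  double v = pm;
  for (int s = m0; s < F; ++s) {
    v *= ((double)(F - s) / (double)(s + 1)) * odds;
    if (v < tiny) break;
    pmf[s + 1] = v; hi = s + 1;
  }
  lo = m0;
  v = pm;
  for (int s = m0; s > 0; --s) {
    v *= ((double)s / (double)(F - s + 1)) / odds;
    if (v < tiny) break;
    pmf[s - 1] = v; lo = s - 1;
  }
}

// truncated Poisson weights, normalised
void pois_weights(double mu, std::vector<double>& w) {
  w.clear();
  if (mu <= 0) { w.push_back(1.0); return; }
  double tot = 0.0;
  for (int j = 0; j < 200; ++j) {
    double d = R::dpois(j, mu, 0);
    w.push_back(d); tot += d;
    if (tot > 1.0 - 1e-8 && j > mu) break;
  }
  for (double& x : w) x /= tot;
}

int find_bin(double v, const NumericVector& edges) {
  // -1 below, nb above; edges increasing
  int nb = edges.size() - 1;
  if (v < edges[0]) return -1;
  if (v >= edges[nb]) return nb;
  int lo = 0, hi = nb;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (v < edges[mid]) hi = mid; else lo = mid; }
  return lo;
}

} // namespace

// [[Rcpp::export]]
List pda_predict_cpp(IntegerVector Ns, NumericVector wN,
                     NumericMatrix p_nodes, NumericMatrix w_nodes,
                     NumericVector fractions, NumericVector obs_edges,
                     int kind, double gammaf, double R0, double gfac,
                     double bg_success, double bg_fail) {
  const int n_states = fractions.size();
  const int n_nodes = p_nodes.nrow();
  const int nb = obs_edges.size() - 1;
  NumericVector hist(nb);
  double censored = 0.0, lost_low = 0.0, lost_high = 0.0;

  std::vector<double> wbs, wbf;   // background weights success/fail channel
  pois_weights(bg_success, wbs);
  pois_weights(bg_fail, wbf);

  std::vector<double> pmf;
  int lo, hi;

  for (int iN = 0; iN < Ns.size(); ++iN) {
    const int N = Ns[iN];
    const double wtot = wN[iN];
    std::vector<double> Ps(N + 1, 0.0);
    double wincl = 0.0;
    for (size_t br = 0; br < wbs.size(); ++br) {
      if ((int)br > N) break;
      for (size_t bg = 0; bg < wbf.size(); ++bg) {
        const int F = N - (int)br - (int)bg;
        if (F < 0) break;
        const double wb = wbs[br] * wbf[bg];
        if (wb < 1e-8) continue;
        wincl += wb;
        for (int st = 0; st < n_states; ++st) {
          const double fs = fractions[st];
          if (fs <= 0) continue;
          for (int nd = 0; nd < n_nodes; ++nd) {
            const double wq = w_nodes(nd, st);
            if (wq <= 0) continue;
            binom_pmf(F, p_nodes(nd, st), pmf, lo, hi);
            const double wall = wb * fs * wq;
            for (int s = lo; s <= hi; ++s)
              Ps[s + br] += wall * pmf[s];
          }
        }
      }
    }
    if (wincl > 0 && wincl < 1.0)
      for (double& x : Ps) x /= wincl;

    // map observed success counts to the observable and histogram
    for (int s = 0; s <= N; ++s) {
      const double mass = wtot * Ps[s];
      if (mass <= 0) continue;
      double val;
      bool cens = false;
      const double Fsucc = s - bg_success;
      const double Ffail = (N - s) - bg_fail;
      if (kind == 0) {
        if (Fsucc <= 0) { cens = true; val = NA_REAL; }
        else {
          double E = Fsucc / (Fsucc + gammaf * std::max(Ffail, 0.0));
          if (E >= 1.0) val = 0.0;
          else val = R0 * std::pow(1.0 / E - 1.0, 1.0 / 6.0);
        }
      } else {
        const double denom = Fsucc + 2.0 * gfac * Ffail;
        if (denom <= 0) { cens = true; val = NA_REAL; }
        else val = (Fsucc - gfac * Ffail) / denom;
      }
      if (cens) { censored += mass; continue; }
      int b = find_bin(val, obs_edges);
      if (b < 0) lost_low += mass;
      else if (b >= nb) lost_high += mass;
      else hist[b] += mass;
    }
  }
  return List::create(_["hist"] = hist, _["censored"] = censored,
                      _["lost_low"] = lost_low, _["lost_high"] = lost_high);
}
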