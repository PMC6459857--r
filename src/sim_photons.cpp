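#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Channel encoding: 1 = G parallel, 2 = G perpendicular,
//                   3 = R parallel, 4 = R perpendicular.

namespace {

struct StatePhys {
  double E;        // FRET efficiency at the currently drawn distance
  double tau;      // donor lifetime (ns)
  double r_ss;     // steady-state donor anisotropy
};

// One row of exp(Q * dt) in spectral form, then sample the next state.
int propagate_state(int cur, double dt, int k,
                    const NumericMatrix& V, const NumericVector& lambda,
                    const NumericMatrix& Vinv, std::vector<double>& buf) {
  if (k == 1) return 0;
  double tot = 0.0;
  for (int j = 0; j < k; ++j) {
    double p = 0.0;
    for (int m = 0; m < k; ++m)
      p += V(cur, m) * std::exp(lambda[m] * dt) * Vinv(m, j);
    if (p < 0) p = 0;
    buf[j] = p; tot += p;
  }
  double u = unif_rand() * tot, acc = 0.0;
  for (int j = 0; j < k; ++j) { acc += buf[j]; if (u <= acc) return j; }
  return k - 1;
}

int sample_discrete(const NumericVector& p) {
  double u = unif_rand(), acc = 0.0;
  for (int j = 0; j < p.size(); ++j) { acc += p[j]; if (u <= acc) return j; }
  return p.size() - 1;
}

double draw_distance(double mu, double sigma) {
  if (!std::isfinite(mu)) return R_PosInf;
  if (sigma <= 0) return mu;
  for (int it = 0; it < 100; ++it) {
    double r = mu + sigma * norm_rand();
    if (r > 1.0) return r;
  }
  return mu;
}

} // namespace

// [[Rcpp::export]]
List sim_photons_cpp(double duration, int mode,
                     NumericVector R_DA, NumericVector sigma_DA,
                     NumericVector tau_D, NumericVector rho,
                     NumericVector r0_state, double R0,
                     NumericMatrix V, NumericVector lambda,
                     NumericMatrix Vinv, NumericVector pi0,
                     double t_diff, double occupancy, double brightness,
                     double g_factor, double det_ratio_gr,
                     double crosstalk, double direct_exc,
                     double tau_A, double r_acceptor,
                     double irf_sigma, double irf_t0, double period,
                     double kappa, double dt_frac) {
  const int k = R_DA.size();
  std::vector<double> buf(k);

  // detection thinning for green/red efficiency imbalance
  const double etaG = det_ratio_gr >= 1.0 ? 1.0 : det_ratio_gr;
  const double etaR = det_ratio_gr >= 1.0 ? 1.0 / det_ratio_gr : 1.0;

  std::vector<double> out_t, out_micro;
  std::vector<int> out_ch, out_mol, out_state;
  std::vector<double> tr_start, tr_stop;
  std::vector<int> tr_n, tr_id;

  auto r_ss_of = [&](int s) {
    return r0_state[s] / (1.0 + tau_D[s] / rho[s]);
  };
  auto E_of = [&](int s, double R) {
    if (!std::isfinite(R)) return 0.0;
    double x = R / R0;
    double x6 = x * x; x6 = x6 * x6 * x6;
    return 1.0 / (1.0 + x6);
  };

  // emit one detected photon at absolute time t for molecule mol in state s
  auto emit = [&](double t, int mol, int s, double E) {
    bool red; double micro;
    bool acceptor_route = false;
    if (direct_exc > 0 && unif_rand() < direct_exc) {
      acceptor_route = true;
      micro = exp_rand() * tau_A;
    } else if (unif_rand() < E) {
      acceptor_route = true;                 // FRET-sensitised
      micro = exp_rand() * tau_D[s] + exp_rand() * tau_A;
    } else {
      micro = exp_rand() * tau_D[s];         // donor emission
    }
    if (acceptor_route) red = true;
    else red = (crosstalk > 0 && unif_rand() < crosstalk);
    // colour-dependent detection efficiency (thinning)
    if (unif_rand() >= (red ? etaR : etaG)) return;
    double r_emit = acceptor_route ? r_acceptor : r_ss_of(s);
    double gp = g_factor * (1.0 + 2.0 * r_emit);
    double p_par = gp / (gp + (1.0 - r_emit));
    bool par = unif_rand() < p_par;
    micro += irf_t0 + irf_sigma * norm_rand();
    micro -= period * std::floor(micro / period);   // wrap into [0, period)
    out_t.push_back(t);
    out_micro.push_back(micro);
    out_ch.push_back(red ? (par ? 3 : 4) : (par ? 1 : 2));
    out_mol.push_back(mol);
    out_state.push_back(s + 1);
  };

  if (mode == 0) {
    // top-hat transits: Poisson arrivals, exponential dwell
    double arrival_rate = occupancy / t_diff;
    double t = 0.0;
    int mol = 0;
    while (true) {
      t += exp_rand() / arrival_rate;
      if (t >= duration) break;
      ++mol;
      double dwell = exp_rand() * t_diff;
      double t_end = std::min(t + dwell, duration);
      // photon times within the transit
      int s = sample_discrete(pi0);
      double R = draw_distance(R_DA[s], sigma_DA[s]);
      double E = E_of(s, R);
      double tp = t;
      int nph = 0;
      while (true) {
        double gap = exp_rand() / brightness;
        double tn = tp + gap;
        if (tn >= t_end) break;
        int s2 = propagate_state(s, tn - tp, k, V, lambda, Vinv, buf);
        if (s2 != s) { s = s2; R = draw_distance(R_DA[s], sigma_DA[s]); E = E_of(s, R); }
        size_t before = out_t.size();
        emit(tn, mol, s, E);
        if (out_t.size() > before) ++nph;
        tp = tn;
      }
      tr_id.push_back(mol);
      tr_start.push_back(t);
      tr_stop.push_back(t_end);
      tr_n.push_back(nph);
      t = t;  // next arrival measured from previous arrival time
    }
  } else {
    // Brownian walk in a periodic box with a 3D-Gaussian detection profile
    const double w0 = 1.0;
    const double Lxy = 8.0 * w0, Lz = 8.0 * w0 * (kappa > 1 ? kappa / 1.0 : 3.0);
    const double Veff = std::pow(M_PI, 1.5) * w0 * w0 * (kappa * w0);
    const double Vbox = Lxy * Lxy * Lz;
    int n_mol = std::max(1, (int)std::lround(occupancy / Veff * Vbox));
    const double D = w0 * w0 / (4.0 * t_diff);
    const double dt = t_diff * dt_frac;
    const double sd_step = std::sqrt(2.0 * D * dt);
    const int n_steps = (int)std::ceil(duration / dt);

    for (int m = 0; m < n_mol; ++m) {
      double x = (unif_rand() - 0.5) * Lxy;
      double y = (unif_rand() - 0.5) * Lxy;
      double z = (unif_rand() - 0.5) * Lz;
      int s = sample_discrete(pi0);
      double R = draw_distance(R_DA[s], sigma_DA[s]);
      double E = E_of(s, R);
      double t_last = 0.0;
      for (int st = 0; st < n_steps; ++st) {
        double t0s = st * dt;
        double W = std::exp(-2.0 * (x * x + y * y) / (w0 * w0)
                            - 2.0 * z * z / (kappa * kappa * w0 * w0));
        double lam = brightness * W * dt;
        if (lam > 1e-12) {
          int nph = (int)R::rpois(lam);
          if (nph > 0) {
            // per-step emission times must be ordered so the Markov state
            // propagation sees true forward time gaps
            std::vector<double> ts(nph);
            for (int p = 0; p < nph; ++p) ts[p] = t0s + unif_rand() * dt;
            std::sort(ts.begin(), ts.end());
            for (int p = 0; p < nph; ++p) {
              double tn = ts[p];
              if (tn >= duration) continue;
              int s2 = propagate_state(s, tn - t_last, k, V, lambda, Vinv, buf);
              if (s2 != s) { s = s2; R = draw_distance(R_DA[s], sigma_DA[s]); E = E_of(s, R); }
              emit(tn, m + 1, s, E);
              t_last = tn;
            }
          }
        }
        x += sd_step * norm_rand(); y += sd_step * norm_rand(); z += sd_step * norm_rand();
        if (x > Lxy / 2) x -= Lxy; else if (x < -Lxy / 2) x += Lxy;
        if (y > Lxy / 2) y -= Lxy; else if (y < -Lxy / 2) y += Lxy;
        if (z > Lz / 2) z -= Lz; else if (z < -Lz / 2) z += Lz;
      }
    }
  }

  return List::create(
    _["t"] = wrap(out_t), _["micro"] = wrap(out_micro),
    _["channel"] = wrap(out_ch), _["molecule"] = wrap(out_mol),
    _["state"] = wrap(out_state),
    _["transit_id"] = wrap(tr_id), _["transit_start"] = wrap(tr_start),
    _["transit_stop"] = wrap(tr_stop), _["transit_n"] = wrap(tr_n));
}
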