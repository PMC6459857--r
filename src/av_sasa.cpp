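#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coarse-grained accessible volume (AV1, single dye sphere).
//
// Candidate dye positions on a cubic grid around the attachment point are
// accepted when (i) they lie within the linker length of the attachment,
// (ii) the dye sphere clears every atom, and (iii) a straight "dial-out"
// path from the attachment to the position keeps a clearance of half the
// linker width from every atom.  Atoms essentially coincident with the
// attachment point (the attachment atom itself) are ignored.

// [[Rcpp::export]]
NumericMatrix compute_av_cpp(NumericVector attach, NumericMatrix atoms,
                             NumericVector radii, double linker_length,
                             double linker_width, double dye_radius,
                             double grid_spacing) {
  const int na = atoms.nrow();
  const double ax = attach[0], ay = attach[1], az = attach[2];
  std::vector<double> axv, ayv, azv, arv;
  for (int i = 0; i < na; ++i) {
    double dx = atoms(i, 0) - ax, dy = atoms(i, 1) - ay, dz = atoms(i, 2) - az;
    if (dx * dx + dy * dy + dz * dz < 0.25) continue;  // attachment atom
    axv.push_back(atoms(i, 0)); ayv.push_back(atoms(i, 1));
    azv.push_back(atoms(i, 2)); arv.push_back(radii[i]);
  }
  const int nk = (int)axv.size();
  const int ng = (int)std::floor(linker_length / grid_spacing);
  const double half_w = linker_width / 2.0;
  const double L2 = linker_length * linker_length;

  std::vector<double> px, py, pz;
  const int nsamp = std::max(3, (int)std::ceil(linker_length / (grid_spacing / 1.5)));
  for (int ix = -ng; ix <= ng; ++ix)
    for (int iy = -ng; iy <= ng; ++iy)
      for (int iz = -ng; iz <= ng; ++iz) {
        double x = ax + ix * grid_spacing, y = ay + iy * grid_spacing,
               z = az + iz * grid_spacing;
        double dx = x - ax, dy = y - ay, dz = z - az;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > L2) continue;
        bool ok = true;
        // dye-sphere clash
        for (int a = 0; a < nk && ok; ++a) {
          double ddx = x - axv[a], ddy = y - ayv[a], ddz = z - azv[a];
          double rr = arv[a] + dye_radius;
          if (ddx * ddx + ddy * ddy + ddz * ddz < rr * rr) ok = false;
        }
        if (!ok) continue;
        // straight-path clearance (dial-out approximation); samples closer
        // to the attachment than the linker width are exempt -- the linker
        // emerges at van-der-Waals contact with its own residue
        double dist = std::sqrt(d2);
        int ns = std::max(2, (int)std::ceil(dist / linker_length * nsamp));
        for (int s = 1; s < ns && ok; ++s) {
          double f = (double)s / ns;
          if (f * dist < linker_width) continue;
          double qx = ax + f * dx, qy = ay + f * dy, qz = az + f * dz;
          for (int a = 0; a < nk; ++a) {
            double ddx = qx - axv[a], ddy = qy - ayv[a], ddz = qz - azv[a];
            double rr = arv[a] + half_w;
            if (ddx * ddx + ddy * ddy + ddz * ddz < rr * rr) { ok = false; break; }
          }
        }
        if (!ok) continue;
        px.push_back(x); py.push_back(y); pz.push_back(z);
      }
  NumericMatrix out(px.size(), 3);
  for (size_t i = 0; i < px.size(); ++i) {
    out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i];
  }
  return out;
}

// Shrake-Rupley solvent-accessible surface area.
// Golden-spiral test points on each atom's solvent-expanded sphere; a point
// is accessible when it lies outside every neighbouring expanded sphere.

// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector area(n);
  // golden spiral unit sphere points
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n_points; ++i) {
    double zi = 1.0 - 2.0 * (i + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - zi * zi));
    double th = golden * i;
    sx[i] = r * std::cos(th); sy[i] = r * std::sin(th); sz[i] = zi;
  }
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    // neighbour list
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double lim = ri + radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double x = coords(i, 0) + ri * sx[p];
      double y = coords(i, 1) + ri * sy[p];
      double z = coords(i, 2) + ri * sz[p];
      bool free_pt = true;
      for (int jj : nb) {
        double dx = x - coords(jj, 0), dy = y - coords(jj, 1), dz = z - coords(jj, 2);
        double rj = radii[jj] + probe;
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * acc / n_points;
  }
  return area;
}
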