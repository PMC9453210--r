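// Shrake-Rupley solvent-accessible surface area.
//
// Each atom is expanded by the probe radius; a deterministic golden-section
// spiral of n_points test points is placed on the expanded sphere and a point
// counts as accessible when it lies outside every neighbor's expanded sphere.
// SASA_i = 4 * pi * (r_i + probe)^2 * accessible_fraction.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static void spiral_points(int n, std::vector<double>& px,
                          std::vector<double>& py, std::vector<double>& pz) {
  px.resize(n); py.resize(n); pz.resize(n);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * k;
    px[k] = r * std::cos(phi);
    py[k] = r * std::sin(phi);
    pz[k] = z;
  }
}

// per-atom SASA for one conformation (x, y, z arrays of length n)
static void sasa_frame(const double* x, const double* y, const double* z,
                       const double* radii, int n, double probe, int n_points,
                       const std::vector<double>& px,
                       const std::vector<double>& py,
                       const std::vector<double>& pz,
                       double* out) {
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    // neighbors whose expanded sphere can clip atom i's test sphere
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      double reach = ri + radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < reach * reach) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = x[i] + ri * px[k];
      double qy = y[i] + ri * py[k];
      double qz = z[i] + ri * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nbr.size(); ++m) {
        int j = nbr[m];
        double rj = radii[j] + probe;
        double dx = qx - x[j], dy = qy - y[j], dz = qz - z[j];
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)n_points;
  }
}

// [[Rcpp::export]]
NumericVector sasa_atoms_cpp(NumericMatrix coords, NumericVector radii,
                             double probe, int n_points) {
  const int n = coords.nrow();
  if (radii.size() != n) stop("radii length must match atom count");
  std::vector<double> px, py, pz, x(n), y(n), z(n);
  spiral_points(n_points, px, py, pz);
  for (int i = 0; i < n; ++i) { x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2); }
  NumericVector out(n);
  sasa_frame(x.data(), y.data(), z.data(), radii.begin(), n, probe, n_points,
             px, py, pz, out.begin());
  return out;
}

// xyz: frames x (3 * n_atoms), bio3d layout (x1, y1, z1, x2, ...).
// site_idx0: 0-based atom indices whose SASA is summed per frame.
// [[Rcpp::export]]
NumericVector sasa_site_series_cpp(NumericMatrix xyz, NumericVector radii,
                                   double probe, int n_points,
                                   IntegerVector site_idx0) {
  const int nf = xyz.nrow();
  const int n = xyz.ncol() / 3;
  if (radii.size() != n) stop("radii length must match atom count");
  for (int s = 0; s < site_idx0.size(); ++s)
    if (site_idx0[s] < 0 || site_idx0[s] >= n) stop("site index out of range");
  std::vector<double> px, py, pz;
  spiral_points(n_points, px, py, pz);
  std::vector<double> x(n), y(n), z(n), per_atom(n);
  NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    for (int i = 0; i < n; ++i) {
      x[i] = xyz(f, 3 * i);
      y[i] = xyz(f, 3 * i + 1);
      z[i] = xyz(f, 3 * i + 2);
    }
    sasa_frame(x.data(), y.data(), z.data(), radii.begin(), n, probe, n_points,
               px, py, pz, per_atom.data());
    double s = 0.0;
    for (int k = 0; k < site_idx0.size(); ++k) s += per_atom[site_idx0[k]];
    out[f] = s;
  }
  return out;
}
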