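#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley accessible surface area by point counting on a deterministic
// golden-spiral sphere lattice. xyz is n x 3, radii are vdW radii; each atom
// is expanded by the probe radius.
// [[Rcpp::export]]
NumericVector cf_sasa_cpp(NumericMatrix xyz, NumericVector radii,
                          double probe, int npts) {
  const int n = xyz.nrow();
  // golden-spiral unit sphere points
  std::vector<double> px(npts), py(npts), pz(npts);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npts; ++k) {
    const double y = 1.0 - 2.0 * (k + 0.5) / npts;
    const double r = std::sqrt(std::max(0.0, 1.0 - y * y));
    const double th = golden * k;
    px[k] = r * std::cos(th);
    py[k] = y;
    pz[k] = r * std::sin(th);
  }
  NumericVector area(n);
  for (int i = 0; i < n; ++i) {
    const double Ri = radii[i] + probe;
    // neighbours whose expanded spheres can occlude atom i
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xyz(j, 0) - xyz(i, 0);
      const double dy = xyz(j, 1) - xyz(i, 1);
      const double dz = xyz(j, 2) - xyz(i, 2);
      const double Rj = radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < (Ri + Rj) * (Ri + Rj)) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npts; ++k) {
      const double qx = xyz(i, 0) + Ri * px[k];
      const double qy = xyz(i, 1) + Ri * py[k];
      const double qz = xyz(i, 2) + Ri * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        const double Rj = radii[j] + probe;
        const double dx = qx - xyz(j, 0);
        const double dy = qy - xyz(j, 1);
        const double dz = qz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)npts;
  }
  return area;
}
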