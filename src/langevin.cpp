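#include <Rcpp.h>
using namespace Rcpp;

// force = -dG/dz for G(z) = sum_i h_i exp(-(z - c_i)^2 / (2 w_i^2))
static inline double pmf_force(double z, const std::vector<double>& c,
                               const std::vector<double>& h,
                               const std::vector<double>& w) {
  double f = 0.0;
  for (size_t i = 0; i < c.size(); ++i) {
    const double d = z - c[i];
    const double w2 = w[i] * w[i];
    f += h[i] * d / w2 * std::exp(-0.5 * d * d / w2);
  }
  return f;
}

// Overdamped Euler-Maruyama propagator on a 1-D Gaussian-sum PMF with an
// optional harmonic umbrella bias and reflecting boundaries. Draws from R's
// RNG stream so set.seed() controls reproducibility.
// [[Rcpp::export]]
NumericVector cf_langevin_cpp(double z0, int steps, double dt, double D,
                              double kT, NumericVector centers,
                              NumericVector heights, NumericVector widths,
                              bool biased, double bias_z0, double bias_k,
                              double zmin, double zmax, int thin) {
  const std::vector<double> c = as<std::vector<double>>(centers);
  const std::vector<double> h = as<std::vector<double>>(heights);
  const std::vector<double> w = as<std::vector<double>>(widths);
  const int nrec = steps / thin;
  NumericVector out(nrec + 1);
  const double pref = D / kT * dt;
  const double noise = std::sqrt(2.0 * D * dt);
  double z = z0;
  out[0] = z;
  int j = 1;
  for (int s = 1; s <= steps; ++s) {
    double f = pmf_force(z, c, h, w);
    if (biased) f -= bias_k * (z - bias_z0);
    z += pref * f + noise * R::norm_rand();
    // reflecting walls; loop handles overshoot beyond both walls
    while (z < zmin || z > zmax) {
      if (z < zmin) z = 2.0 * zmin - z;
      if (z > zmax) z = 2.0 * zmax - z;
    }
    if (s % thin == 0) out[j++] = z;
  }
  return out;
}
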