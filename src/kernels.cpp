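// Inner loops for MSD accumulation and overdamped Langevin integration.
// All randomness comes from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

// dF/dx in kT per coordinate unit for the profile families.
// fam: 0 = flat, 1 = piecewise_parabola, 2 = quartic_smooth,
//      3 = harmonic well F = 0.5 * B * (x - xts)^2 (B = kappa, xts = centre)
static inline double dFdx(double x, int fam, double L, double xts,
                          double B) {
  if (fam == 0) return 0.0;
  if (fam == 3) return B * (x - xts);
  double w = (x <= xts) ? xts : (L - xts);
  double s = (x - xts) / w;
  if (fam == 1) return -2.0 * B * s / w;
  return -4.0 * B * s * (1.0 - s * s) / w;
}

// [[Rcpp::export]]
List cpp_msd(NumericVector x, IntegerVector lags) {
  int n = x.size(), m = lags.size();
  NumericVector msd(m);
  IntegerVector np(m);
  for (int j = 0; j < m; ++j) {
    int k = lags[j];
    if (k <= 0 || k >= n) {
      msd[j] = NA_REAL;
      np[j] = 0;
      continue;
    }
    double s = 0.0;
    for (int i = 0; i + k < n; ++i) {
      double d = x[i + k] - x[i];
      s += d * d;
    }
    np[j] = n - k;
    msd[j] = s / np[j];
  }
  return List::create(_["msd"] = msd, _["n_pairs"] = np);
}

// Euler-Maruyama path; reflecting walls at [0, L] when reflect is true.
// [[Rcpp::export]]
NumericVector cpp_langevin_path(double x0, int nSteps, double dt, double D,
                                int fam, double L, double xts, double B,
                                bool reflect) {
  NumericVector out(nSteps + 1);
  double x = x0, sd = std::sqrt(2.0 * D * dt);
  out[0] = x;
  for (int i = 1; i <= nSteps; ++i) {
    x += -D * dFdx(x, fam, L, xts, B) * dt + sd * norm_rand();
    if (reflect) {
      while (x < 0.0 || x > L) {
        if (x < 0.0) x = -x;
        if (x > L) x = 2.0 * L - x;
      }
    }
    out[i] = x;
  }
  return out;
}

// First-passage times from x0 (reflecting at 0) to the absorbing
// boundary at L.  NA when a passage exceeds maxSteps.
// [[Rcpp::export]]
NumericVector cpp_first_passage(int n, double x0, double dt, double D,
                                int fam, double L, double xts, double B,
                                double maxSteps) {
  NumericVector out(n);
  double sd = std::sqrt(2.0 * D * dt);
  for (int r = 0; r < n; ++r) {
    double x = x0, steps = 0.0;
    bool done = false;
    while (!done) {
      x += -D * dFdx(x, fam, L, xts, B) * dt + sd * norm_rand();
      steps += 1.0;
      if (x < 0.0) x = -x;
      if (x >= L) {
        out[r] = steps * dt;
        done = true;
      } else if (steps >= maxSteps) {
        out[r] = NA_REAL;
        done = true;
      }
    }
    if ((r & 0x3ff) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
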