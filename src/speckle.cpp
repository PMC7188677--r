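#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dynamic-speckle forward model. Per pixel, a complex circular-Gaussian field
// evolves across substeps of one exposure with lag-l autocorrelation
// exp(-l*dt/tau); the recorded intensity is the substep-mean of
// |sqrt(rho)*E_dyn + sqrt(1-rho)*E_static|^2, scaled so E[I] = mean_intensity.
// Pixels are mutually independent (fully developed speckle, one speckle per
// pixel). Frames are independent realizations of the dynamic field; the static
// field and any non-finite-tau "frozen" pixels are drawn once per stack.
// Uses R's RNG so set.seed() controls reproducibility.
// [[Rcpp::export]]
NumericVector sim_stack_cpp(NumericVector tau, NumericVector rho,
                            int n_frames, int n_substeps, double dt,
                            double mean_intensity) {
  const int npx = tau.size();
  NumericVector out(static_cast<R_xlen_t>(npx) * n_frames);

  std::vector<double> a(npx), s(npx), sr(npx), ss(npx);
  std::vector<bool> frozen(npx);
  for (int p = 0; p < npx; ++p) {
    frozen[p] = !std::isfinite(tau[p]);
    a[p] = frozen[p] ? 1.0 : std::exp(-dt / tau[p]);
    s[p] = std::sqrt(std::max(0.0, 1.0 - a[p] * a[p]));
    sr[p] = std::sqrt(rho[p]);
    ss[p] = std::sqrt(1.0 - rho[p]);
  }

  const double inv_sqrt2 = 1.0 / std::sqrt(2.0);
  // static scatterer field, one realization per stack (unit mean intensity)
  std::vector<double> es_re(npx), es_im(npx);
  for (int p = 0; p < npx; ++p) {
    es_re[p] = norm_rand() * inv_sqrt2;
    es_im[p] = norm_rand() * inv_sqrt2;
  }
  // frozen dynamic field for tau = Inf pixels, also one realization per stack
  std::vector<double> ez_re(npx), ez_im(npx);
  for (int p = 0; p < npx; ++p) {
    ez_re[p] = norm_rand() * inv_sqrt2;
    ez_im[p] = norm_rand() * inv_sqrt2;
  }

  std::vector<double> ed_re(npx), ed_im(npx), acc(npx);
  for (int f = 0; f < n_frames; ++f) {
    for (int p = 0; p < npx; ++p) {
      if (frozen[p]) {
        ed_re[p] = ez_re[p];
        ed_im[p] = ez_im[p];
      } else {
        ed_re[p] = norm_rand() * inv_sqrt2;
        ed_im[p] = norm_rand() * inv_sqrt2;
      }
      acc[p] = 0.0;
    }
    for (int k = 0; k < n_substeps; ++k) {
      for (int p = 0; p < npx; ++p) {
        if (k > 0 && !frozen[p]) {
          ed_re[p] = a[p] * ed_re[p] + s[p] * norm_rand() * inv_sqrt2;
          ed_im[p] = a[p] * ed_im[p] + s[p] * norm_rand() * inv_sqrt2;
        }
        const double re = sr[p] * ed_re[p] + ss[p] * es_re[p];
        const double im = sr[p] * ed_im[p] + ss[p] * es_im[p];
        acc[p] += re * re + im * im;
      }
    }
    const double scale = mean_intensity / n_substeps;
    double *frame = &out[static_cast<R_xlen_t>(npx) * f];
    for (int p = 0; p < npx; ++p) frame[p] = acc[p] * scale;
  }
  return out;
}

// Windowed speckle contrast K = sigma/<I> with population (divide-by-N) sigma.
// The neighborhood is the window x window square clipped to the image
// (shrink-to-valid border, no padding) and restricted to valid pixels.
// Accumulation is two-pass in long double, column-major, so a brute-force R
// oracle summing the same values agrees to floating tolerance.
// [[Rcpp::export]]
List spatial_contrast_cpp(NumericMatrix img, LogicalMatrix valid, int window) {
  const int nr = img.nrow(), nc = img.ncol(), h = window / 2;
  NumericMatrix K(nr, nc), mean_out(nr, nc);
  IntegerMatrix count(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int j0 = std::max(0, j - h), j1 = std::min(nc - 1, j + h);
    for (int i = 0; i < nr; ++i) {
      const int i0 = std::max(0, i - h), i1 = std::min(nr - 1, i + h);
      long double sum = 0.0L;
      int n = 0;
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          if (valid(ii, jj)) { sum += img(ii, jj); ++n; }
      count(i, j) = n;
      if (n == 0) { K(i, j) = NA_REAL; mean_out(i, j) = NA_REAL; continue; }
      const long double m = sum / n;
      long double ssq = 0.0L;
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          if (valid(ii, jj)) {
            const long double d = img(ii, jj) - m;
            ssq += d * d;
          }
      mean_out(i, j) = static_cast<double>(m);
      K(i, j) = m > 0 ? static_cast<double>(std::sqrt(ssq / n) / m) : NA_REAL;
    }
  }
  return List::create(_["K"] = K, _["mean"] = mean_out, _["count"] = count);
}
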