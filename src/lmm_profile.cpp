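#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Random-intercept Gaussian mixed model, fitted by maximum likelihood with
// the variance ratio lambda = sigma2_group / sigma2_residual profiled out.
// For V* = I + lambda * Z Z' (Z the group indicator matrix) the inverse and
// determinant have closed forms per group (compound symmetry):
//   V*^{-1} = I - Z diag(w_k) Z',  w_k = lambda / (1 + n_k * lambda)
//   log|V*|  = sum_k log(1 + n_k * lambda)
// so every quantity needed for the profiled deviance is a function of group
// sums, evaluated in O(n). The design matrix has at most two columns
// (intercept, two-level factor contrast).

struct ProfFit {
  double dev;
  double beta0;
  double beta1;
  double sigma2;
  double lambda;
};

// profiled deviance at fixed lambda; X given as 0/1 contrast column (or
// absent when p == 1). g is a 0-based group index.
static ProfFit eval_lambda(const double *y, const int *x, int n, int p,
                           const int *g, const std::vector<int> &nk,
                           double lambda) {
  int K = (int)nk.size();
  std::vector<double> Sy(K, 0.0), Sx(K, 0.0), Sn(K, 0.0);
  double yty = 0.0, xty = 0.0, xtx = 0.0, sy = 0.0, sx = 0.0;
  for (int i = 0; i < n; i++) {
    double yi = y[i];
    yty += yi * yi;
    sy += yi;
    Sy[g[i]] += yi;
    if (p == 2) {
      double xi = (double)x[i];
      xty += xi * yi;
      xtx += xi * xi;
      sx += xi;
      Sx[g[i]] += xi;
    }
  }
  double logdet = 0.0;
  // whitened cross-products: subtract sum_k w_k * S_k S_k'
  double a11 = (double)n, a12 = sx, a22 = xtx; // X'V X entries (col0 = 1)
  double b1 = sy, b2 = xty;                    // X'V y
  double q = yty;                              // y'V y
  for (int k = 0; k < K; k++) {
    double w = lambda / (1.0 + nk[k] * lambda);
    logdet += std::log1p(nk[k] * lambda);
    double sk = (double)nk[k];
    a11 -= w * sk * sk;
    b1 -= w * sk * Sy[k];
    q -= w * Sy[k] * Sy[k];
    if (p == 2) {
      a12 -= w * sk * Sx[k];
      a22 -= w * Sx[k] * Sx[k];
      b2 -= w * Sx[k] * Sy[k];
    }
  }
  ProfFit f;
  f.lambda = lambda;
  double rss;
  if (p == 2) {
    double det = a11 * a22 - a12 * a12;
    if (det <= 0 || !std::isfinite(det)) det = 1e-300;
    f.beta0 = (a22 * b1 - a12 * b2) / det;
    f.beta1 = (a11 * b2 - a12 * b1) / det;
    rss = q - f.beta0 * b1 - f.beta1 * b2;
  } else {
    f.beta0 = b1 / a11;
    f.beta1 = NA_REAL;
    rss = q - f.beta0 * b1;
  }
  if (rss < 1e-300) rss = 1e-300;
  f.sigma2 = rss / n;
  f.dev = n * std::log(2.0 * M_PI * f.sigma2) + logdet + n;
  return f;
}

// minimise the profiled deviance over lambda >= 0: coarse grid on log scale
// (plus the lambda = 0 boundary), then golden-section refinement.
static ProfFit fit_one(const double *y, const int *x, int n, int p,
                       const int *g, const std::vector<int> &nk) {
  const int NG = 41;
  double best_s = R_NegInf; // s = log(lambda); -Inf encodes lambda = 0
  ProfFit best = eval_lambda(y, x, n, p, g, nk, 0.0);
  double grid[NG];
  for (int i = 0; i < NG; i++) grid[i] = -10.0 + 20.0 * i / (NG - 1);
  int best_i = -1;
  for (int i = 0; i < NG; i++) {
    ProfFit f = eval_lambda(y, x, n, p, g, nk, std::exp(grid[i]));
    if (f.dev < best.dev) { best = f; best_s = grid[i]; best_i = i; }
  }
  if (best_i >= 0) {
    double lo = (best_i == 0) ? grid[0] - 0.5 : grid[best_i - 1];
    double hi = (best_i == NG - 1) ? grid[NG - 1] + 0.5 : grid[best_i + 1];
    const double gr = 0.6180339887498949;
    double c = hi - gr * (hi - lo), d = lo + gr * (hi - lo);
    ProfFit fc = eval_lambda(y, x, n, p, g, nk, std::exp(c));
    ProfFit fd = eval_lambda(y, x, n, p, g, nk, std::exp(d));
    for (int it = 0; it < 60 && (hi - lo) > 1e-9; it++) {
      if (fc.dev < fd.dev) {
        hi = d; d = c; fd = fc;
        c = hi - gr * (hi - lo);
        fc = eval_lambda(y, x, n, p, g, nk, std::exp(c));
      } else {
        lo = c; c = d; fc = fd;
        d = lo + gr * (hi - lo);
        fd = eval_lambda(y, x, n, p, g, nk, std::exp(d));
      }
    }
    ProfFit f = (fc.dev < fd.dev) ? fc : fd;
    if (f.dev < best.dev) best = f;
  }
  (void)best_s;
  return best;
}

static std::vector<int> group_sizes(const IntegerVector &g, int K) {
  std::vector<int> nk(K, 0);
  for (int i = 0; i < g.size(); i++) nk[g[i]]++;
  return nk;
}

//' @noRd
// [[Rcpp::export(name = ".lmm_profile_fit")]]
List lmm_profile_fit(NumericVector y, IntegerVector xcontrast, IntegerVector g,
                     int ngroups, bool with_contrast) {
  int n = y.size();
  std::vector<int> nk = group_sizes(g, ngroups);
  ProfFit f = fit_one(REAL(y), with_contrast ? INTEGER(xcontrast) : (int *)0,
                      n, with_contrast ? 2 : 1, INTEGER(g), nk);
  return List::create(
      _["beta0"] = f.beta0, _["beta1"] = f.beta1,
      _["sigma2_residual"] = f.sigma2,
      _["sigma2_group"] = f.lambda * f.sigma2,
      _["deviance"] = f.dev, _["logLik"] = -0.5 * f.dev);
}

// Deviance change (null minus full) for the observed response and for each
// column of a 1-based permutation-index matrix applied to the response.
//' @noRd
// [[Rcpp::export(name = ".lmm_perm_devchange")]]
NumericVector lmm_perm_devchange(NumericVector z, IntegerMatrix perms,
                                 IntegerVector xcontrast, IntegerVector g,
                                 int ngroups) {
  int n = z.size(), np = perms.ncol();
  std::vector<int> nk = group_sizes(g, ngroups);
  NumericVector out(np);
  std::vector<double> zp(n);
  for (int j = 0; j < np; j++) {
    for (int i = 0; i < n; i++) zp[i] = z[perms(i, j) - 1];
    ProfFit full = fit_one(&zp[0], INTEGER(xcontrast), n, 2, INTEGER(g), nk);
    ProfFit null = fit_one(&zp[0], (int *)0, n, 1, INTEGER(g), nk);
    double d = null.dev - full.dev;
    if (d < 0 && d > -1e-6) d = 0.0; // numerical guard on nested fits
    out[j] = d;
  }
  return out;
}
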