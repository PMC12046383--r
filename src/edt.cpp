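#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

// Exact Euclidean squared distance transform of a binary feature mask on a
// regular grid with (possibly anisotropic) spacing, by the separable
// lower-envelope-of-parabolas algorithm (Felzenszwalb & Huttenlocher 2012),
// generalised to arbitrary sample positions x_i = i * h along each axis.

static const double INF = std::numeric_limits<double>::infinity();

// 1D distance transform of sampled function f at positions x[i] = i*h.
// d[i] = min_j ( (x_i - x_j)^2 + f[j] )
static void dt1d(const std::vector<double>& f, double h, std::vector<double>& d) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double xq = q * h;
    while (true) {
      double xv = v[k] * h;
      double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (s <= z[k]) { --k; }
      else {
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
        break;
      }
    }
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[j + 1] < xq) ++j;
    double xv = v[j] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[j]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
Rcpp::NumericVector edt_sq(Rcpp::LogicalVector mask,
                           Rcpp::IntegerVector dim,
                           Rcpp::NumericVector spacing) {
  int nd = dim.size();
  if (nd < 1 || nd > 3) Rcpp::stop("dim must have 1-3 entries");
  if (spacing.size() != nd) Rcpp::stop("spacing length must match dim");
  long n = 1;
  for (int i = 0; i < nd; ++i) n *= dim[i];
  if ((long)mask.size() != n) Rcpp::stop("mask length does not match dim");

  std::vector<double> g(n);
  bool any_feature = false;
  for (long i = 0; i < n; ++i) {
    bool on = (mask[i] == TRUE);
    g[i] = on ? 0.0 : INF;
    any_feature = any_feature || on;
  }
  Rcpp::NumericVector out(n);
  if (!any_feature) {
    std::fill(out.begin(), out.end(), R_PosInf);
    out.attr("dim") = dim;
    return out;
  }

  int d0 = dim[0];
  int d1 = nd > 1 ? dim[1] : 1;
  int d2 = nd > 2 ? dim[2] : 1;

  std::vector<double> f, dline;
  // axis 0 (fastest-varying)
  f.resize(d0); dline.resize(d0);
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j) {
      long base = (long)k * d1 * d0 + (long)j * d0;
      for (int i = 0; i < d0; ++i) f[i] = g[base + i];
      dt1d(f, spacing[0], dline);
      for (int i = 0; i < d0; ++i) g[base + i] = dline[i];
    }
  // axis 1
  if (nd > 1) {
    f.resize(d1); dline.resize(d1);
    for (int k = 0; k < d2; ++k)
      for (int i = 0; i < d0; ++i) {
        long base = (long)k * d1 * d0 + i;
        for (int j = 0; j < d1; ++j) f[j] = g[base + (long)j * d0];
        dt1d(f, spacing[1], dline);
        for (int j = 0; j < d1; ++j) g[base + (long)j * d0] = dline[j];
      }
  }
  // axis 2
  if (nd > 2) {
    f.resize(d2); dline.resize(d2);
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        long base = (long)j * d0 + i;
        for (int k = 0; k < d2; ++k) f[k] = g[base + (long)k * d1 * d0];
        dt1d(f, spacing[2], dline);
        for (int k = 0; k < d2; ++k) g[base + (long)k * d1 * d0] = dline[k];
      }
  }
  for (long i = 0; i < n; ++i) out[i] = g[i];
  out.attr("dim") = dim;
  return out;
}
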