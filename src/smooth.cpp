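#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Tricube-kernel weighted running mean over irregularly spaced sites.
//
// pos must be sorted ascending (one chromosome at a time). Values may be NA
// (e.g. a replicate with zero coverage at a retained site); NA values get
// zero weight. The window is [pos[i]-h, pos[i]+h]; when it holds fewer than
// min_sites sites (NA or not) the half-width is doubled until it does or the
// window spans the whole chromosome. The kernel distance is scaled by h+1 so
// boundary sites keep strictly positive weight.
// [[Rcpp::export]]
NumericVector smooth_tricube_cpp(IntegerVector pos, NumericVector x,
                                 double half_width, int min_sites) {
  const int n = pos.size();
  if (x.size() != n) stop("pos and x lengths differ");
  NumericVector out(n);
  const int* p = INTEGER(pos);
  for (int i = 0; i < n; ++i) {
    double h = half_width;
    int lo, hi; // [lo, hi) index window
    for (;;) {
      lo = std::lower_bound(p, p + n, (double)p[i] - h) - p;
      hi = std::upper_bound(p, p + n, (double)p[i] + h) - p;
      if (hi - lo >= min_sites || (lo == 0 && hi == n)) break;
      h *= 2.0;
    }
    double sw = 0.0, swx = 0.0;
    const double scale = h + 1.0;
    for (int j = lo; j < hi; ++j) {
      if (NumericVector::is_na(x[j])) continue;
      double u = std::abs((double)p[j] - (double)p[i]) / scale;
      double a = 1.0 - u * u * u;
      double w = a * a * a;
      sw += w;
      swx += w * x[j];
    }
    out[i] = (sw > 0.0) ? swx / sw : NA_REAL;
  }
  return out;
}
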