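#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sampling of an image at arbitrary (row, col) positions,
// 1-based coordinates; samples falling outside the grid contribute 0.
// Shared by real-space rotation and polar resampling, which dominate the
// cost of the alignment loop.
// [[Rcpp::export(name = ".bilinear_sample")]]
NumericVector bilinear_sample(const NumericMatrix img,
                              const NumericVector row,
                              const NumericVector col) {
  const int n = row.size();
  const int nr = img.nrow(), nc = img.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double r = row[i] - 1.0;  // 0-based
    const double c = col[i] - 1.0;
    const int r0 = (int)std::floor(r);
    const int c0 = (int)std::floor(c);
    const double fr = r - r0, fc = c - c0;
    double v = 0.0;
    const double w00 = (1.0 - fr) * (1.0 - fc);
    const double w01 = (1.0 - fr) * fc;
    const double w10 = fr * (1.0 - fc);
    const double w11 = fr * fc;
    if (r0 >= 0 && r0 < nr) {
      if (c0 >= 0 && c0 < nc && w00 != 0.0) v += w00 * img(r0, c0);
      if (c0 + 1 >= 0 && c0 + 1 < nc && w01 != 0.0) v += w01 * img(r0, c0 + 1);
    }
    if (r0 + 1 >= 0 && r0 + 1 < nr) {
      if (c0 >= 0 && c0 < nc && w10 != 0.0) v += w10 * img(r0 + 1, c0);
      if (c0 + 1 >= 0 && c0 + 1 < nc && w11 != 0.0) v += w11 * img(r0 + 1, c0 + 1);
    }
    out[i] = v;
  }
  return out;
}
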