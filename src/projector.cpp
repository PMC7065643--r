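#include <Rcpp.h>
using namespace Rcpp;

// Parallel-beam projector pair. Pixel-driven with linear splatting onto the
// detector: each pixel's value is distributed between the two detector bins
// bracketing its signed distance t from the rotation axis. The backprojector
// gathers with the same weights, so <R x, y> == <x, R^T y> holds to floating
// precision by construction (required by the iterative TV solver).
//
// Conventions shared across the package:
//  - images are square H x H, rotation axis at pixel center ((H-1)/2, (H-1)/2)
//  - angles in radians, measured counterclockwise from the image x axis
//    (x = column index, y = row index)
//  - detector has H bins, bin b covers signed distance t = b - (H-1)/2

// [[Rcpp::export]]
NumericMatrix cpp_radon(const NumericMatrix& img, const NumericVector& angles_rad) {
  const int H = img.nrow(), W = img.ncol();
  const int nA = angles_rad.size();
  const double c = 0.5 * (H - 1);
  NumericMatrix sino(H, nA);
  for (int a = 0; a < nA; ++a) {
    const double co = std::cos(angles_rad[a]);
    const double si = std::sin(angles_rad[a]);
    for (int j = 0; j < W; ++j) {
      const double xc = (j - c) * co;
      for (int i = 0; i < H; ++i) {
        const double v = img(i, j);
        if (v == 0.0) continue;
        const double t = xc + (i - c) * si + c;
        const int k = (int)std::floor(t);
        const double w = t - k;
        if (k >= 0 && k < H) sino(k, a) += v * (1.0 - w);
        if (k + 1 >= 0 && k + 1 < H) sino(k + 1, a) += v * w;
      }
    }
  }
  return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_backproject(const NumericMatrix& sino, const NumericVector& angles_rad,
                              const int size) {
  const int H = size;
  const int det = sino.nrow();
  const int nA = angles_rad.size();
  const double c = 0.5 * (H - 1);
  const double cd = 0.5 * (det - 1);
  NumericMatrix img(H, H);
  for (int a = 0; a < nA; ++a) {
    const double co = std::cos(angles_rad[a]);
    const double si = std::sin(angles_rad[a]);
    for (int j = 0; j < H; ++j) {
      const double xc = (j - c) * co;
      for (int i = 0; i < H; ++i) {
        const double t = xc + (i - c) * si + cd;
        const int k = (int)std::floor(t);
        const double w = t - k;
        double acc = 0.0;
        if (k >= 0 && k < det) acc += sino(k, a) * (1.0 - w);
        if (k + 1 >= 0 && k + 1 < det) acc += sino(k + 1, a) * w;
        img(i, j) += acc;
      }
    }
  }
  return img;
}
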