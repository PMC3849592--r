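#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Assign every pixel of an nrow x ncol grid to the seed with the smallest
// power distance ||p - s_i||^2 - w_i, and record the pixel's perpendicular
// distance to the bisector between its best and second-best seeds. That
// distance is the pixel's distance to the (power-diagram) cell boundary,
// which is what the membrane-rim painting needs. Pixel centers are at
// (col, row) in 1-based coordinates, x = column, y = row.
//
// [[Rcpp::export]]
List power_assign(int nrow, int ncol, NumericVector sx, NumericVector sy,
                  NumericVector w) {
  const int n = sx.size();
  IntegerMatrix lab(nrow, ncol);
  NumericMatrix edged(nrow, ncol);
  for (int c = 0; c < ncol; ++c) {
    const double x = c + 1.0;
    for (int r = 0; r < nrow; ++r) {
      const double y = r + 1.0;
      double b1 = R_PosInf, b2 = R_PosInf;
      int i1 = -1, i2 = -1;
      for (int i = 0; i < n; ++i) {
        const double dx = x - sx[i];
        const double dy = y - sy[i];
        const double pd = dx * dx + dy * dy - w[i];
        if (pd < b1) {
          b2 = b1; i2 = i1;
          b1 = pd; i1 = i;
        } else if (pd < b2) {
          b2 = pd; i2 = i;
        }
      }
      lab(r, c) = i1 + 1;
      if (i2 < 0) {
        edged(r, c) = R_PosInf;
      } else {
        const double dx = sx[i1] - sx[i2];
        const double dy = sy[i1] - sy[i2];
        const double ds = std::sqrt(dx * dx + dy * dy);
        edged(r, c) = ds > 0 ? (b2 - b1) / (2.0 * ds) : 0.0;
      }
    }
  }
  return List::create(_["label"] = lab, _["edge_dist"] = edged);
}
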