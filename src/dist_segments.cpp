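#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum Euclidean distance from each point (px, py) to a set of segments
// (ax, ay) - (bx, by). Used for signed-distance construction from a contour
// polyline and for boundary-error metrics.
// [[Rcpp::export]]
NumericVector dist_to_segments_cpp(NumericVector px, NumericVector py,
                                   NumericVector ax, NumericVector ay,
                                   NumericVector bx, NumericVector by) {
  const int n = px.size();
  const int m = ax.size();
  if (py.size() != n || ay.size() != m || bx.size() != m || by.size() != m)
    stop("dist_to_segments: length mismatch");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double x = px[i], y = py[i];
    for (int s = 0; s < m; ++s) {
      double abx = bx[s] - ax[s], aby = by[s] - ay[s];
      double dx = x - ax[s], dy = y - ay[s];
      double len2 = abx * abx + aby * aby;
      double d2;
      if (len2 < 1e-300) {
        d2 = dx * dx + dy * dy;
      } else {
        double t = (dx * abx + dy * aby) / len2;
        if (t < 0) t = 0; else if (t > 1) t = 1;
        double ex = dx - t * abx, ey = dy - t * aby;
        d2 = ex * ex + ey * ey;
      }
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
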