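#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Interior reaction-diffusion substeps for the moving-boundary solver.
// The tumor region is {phi < 0}. Second derivatives use Gibou-Fedkiw
// cut-cell stencils where a neighbour lies across the interface, imposing
// u = ubar exactly at the linear interface crossing; faces into wall pixels
// (outside the brain or in ventricles) are reflected (no-flux). Pixels closer
// to the interface than theta_min * h on both sides of an axis are pinned to
// ubar. Performs nsub explicit Euler substeps of length dt with phi frozen.
// [[Rcpp::export]]
NumericMatrix ls_update_u_cpp(NumericMatrix u_, NumericMatrix phi,
                              LogicalMatrix wall, NumericMatrix Dx,
                              NumericMatrix Dy, double hx, double hy,
                              double rho, double dt, int nsub, double ubar,
                              double theta_min) {
  const int nx = u_.nrow(), ny = u_.ncol();
  NumericMatrix u(clone(u_));
  NumericMatrix unew(nx, ny);
  // classify once (phi frozen during the substeps)
  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if (!(phi(i, j) < 0) || wall(i, j)) { unew(i, j) = u(i, j); continue; }
        const double ui = u(i, j);
        const double pij = phi(i, j);
        // axis stencil helper: returns second difference with cut cells
        double lap = 0.0;
        bool pin = false;
        for (int ax = 0; ax < 2; ++ax) {
          const double h = ax == 0 ? hx : hy;
          double uL, uR, thL = 1.0, thR = 1.0;
          // left neighbour
          {
            int ii = ax == 0 ? i - 1 : i;
            int jj = ax == 0 ? j : j - 1;
            if (ii < 0 || jj < 0 || wall(ii, jj)) {
              uL = ui;  // no-flux mirror
            } else if (phi(ii, jj) < 0) {
              uL = u(ii, jj);
            } else {
              thL = pij / (pij - phi(ii, jj));  // in (0, 1]
              uL = ubar;
            }
          }
          // right neighbour
          {
            int ii = ax == 0 ? i + 1 : i;
            int jj = ax == 0 ? j : j + 1;
            if (ii >= nx || jj >= ny || wall(ii, jj)) {
              uR = ui;
            } else if (phi(ii, jj) < 0) {
              uR = u(ii, jj);
            } else {
              thR = pij / (pij - phi(ii, jj));
              uR = ubar;
            }
          }
          if (thL < theta_min && thR < theta_min) { pin = true; break; }
          if (thL < theta_min) { thL = theta_min; }
          if (thR < theta_min) { thR = theta_min; }
          const double D = ax == 0 ? Dx(i, j) : Dy(i, j);
          lap += D * 2.0 *
            (uL / (thL * (thL + thR)) - ui / (thL * thR) +
             uR / (thR * (thL + thR))) / (h * h);
        }
        if (pin) { unew(i, j) = ubar; continue; }
        double val = ui + dt * (lap + rho * ui * (1.0 - ui));
        if (val < 0) val = 0; else if (val > 1) val = 1;
        unew(i, j) = val;
      }
    }
    // swap
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) u(i, j) = unew(i, j);
  }
  return u;
}
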