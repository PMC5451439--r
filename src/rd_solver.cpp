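#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Flux-form reaction-diffusion right-hand side on the masked domain.
// u: density at the domain voxels (vector, domain ordering)
// nbr: n x 6 matrix of 0-based neighbour indices into the domain vector,
//      -1 where the face adjoins a non-domain voxel (no-flux: zero face flux)
// w:   length-6 face weights D/h^2 for (x-, x+, y-, y+, z-, z+), mm^2/h / mm^2
// rho: logistic growth rate (1/h)
static void rd_rhs(const double* u, double* du, const int* nbr, int n,
                   const double* w, double rho) {
  for (int i = 0; i < n; ++i) {
    double lap = 0.0;
    const int* nb = nbr + (size_t)i * 6;
    for (int f = 0; f < 6; ++f) {
      int j = nb[f];
      if (j >= 0) lap += w[f] * (u[j] - u[i]);
    }
    du[i] = lap + rho * u[i] * (1.0 - u[i]);
  }
}

// [[Rcpp::export]]
NumericVector rd_rhs_cpp(NumericVector u, IntegerMatrix nbr, NumericVector w,
                         double rho) {
  int n = u.size();
  if (nbr.nrow() != n || nbr.ncol() != 6) stop("nbr must be n x 6");
  // column-major IntegerMatrix: repack row-wise for locality
  std::vector<int> nb((size_t)n * 6);
  for (int f = 0; f < 6; ++f)
    for (int i = 0; i < n; ++i) nb[(size_t)i * 6 + f] = nbr(i, f);
  NumericVector du(n);
  rd_rhs(u.begin(), du.begin(), nb.data(), n, w.begin(), rho);
  return du;
}

// Adaptive embedded Dormand-Prince 4(5) with FSAL, stepping exactly onto the
// requested output times. Returns an n x length(times) matrix of states.
// Throws if the error control cannot make progress or the solution leaves
// [-clamp, 1 + clamp] (instability detection; no clamping is applied).
// [[Rcpp::export]]
NumericMatrix rd_integrate_cpp(NumericVector u0, IntegerMatrix nbr,
                               NumericVector w, double rho, double t0,
                               NumericVector times, double rtol, double atol,
                               double hmax, double clamp) {
  const int n = u0.size();
  const int nt = times.size();
  if (nbr.nrow() != n || nbr.ncol() != 6) stop("nbr must be n x 6");
  for (int k = 0; k < nt; ++k)
    if (times[k] <= t0 + 1e-12 || (k > 0 && times[k] <= times[k - 1]))
      stop("output times must be strictly increasing and > t0");

  std::vector<int> nb((size_t)n * 6);
  for (int f = 0; f < 6; ++f)
    for (int i = 0; i < n; ++i) nb[(size_t)i * 6 + f] = nbr(i, f);

  // Dormand-Prince coefficients
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  std::vector<double> y(u0.begin(), u0.end()), ynew(n), ytmp(n);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);
  NumericMatrix out(n, nt);

  double t = t0;
  rd_rhs(y.data(), k1.data(), nb.data(), n, w.begin(), rho);
  // initial step guess: modest fraction of the first output interval
  double h = (times[0] - t0) / 100.0;
  if (hmax > 0 && h > hmax) h = hmax;
  int iout = 0;
  long n_steps = 0;
  const long max_steps = 2000000L;

  while (iout < nt) {
    if (++n_steps > max_steps) stop("rd_integrate: step limit exceeded");
    if (hmax > 0 && h > hmax) h = hmax;
    double t_target = times[iout];
    bool hit = false;
    double hs = h;  // step actually attempted (clipped to land on outputs)
    if (t + hs >= t_target - 1e-12 * std::max(1.0, std::abs(t_target))) {
      hs = t_target - t;
      hit = true;
    }
    if (hs <= 1e-12 * std::max(1.0, std::abs(t)))
      stop("rd_integrate: step size underflow (solver failed at tolerances)");

    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + hs * a21 * k1[i];
    rd_rhs(ytmp.data(), k2.data(), nb.data(), n, w.begin(), rho);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + hs * (a31 * k1[i] + a32 * k2[i]);
    rd_rhs(ytmp.data(), k3.data(), nb.data(), n, w.begin(), rho);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + hs * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rd_rhs(ytmp.data(), k4.data(), nb.data(), n, w.begin(), rho);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + hs * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rd_rhs(ytmp.data(), k5.data(), nb.data(), n, w.begin(), rho);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + hs * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                             a64 * k4[i] + a65 * k5[i]);
    rd_rhs(ytmp.data(), k6.data(), nb.data(), n, w.begin(), rho);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + hs * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                             b5 * k5[i] + b6 * k6[i]);
    rd_rhs(ynew.data(), k7.data(), nb.data(), n, w.begin(), rho);

    double err2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = hs * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                       e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::abs(y[i]), std::abs(ynew[i]));
      double r = e / sc;
      err2 += r * r;
    }
    double err = std::sqrt(err2 / n);
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);

    if (err <= 1.0) {
      t += hs;
      std::swap(y, ynew);
      std::swap(k1, k7);  // FSAL
      if (hit) {
        for (int i = 0; i < n; ++i) {
          if (y[i] < -clamp || y[i] > 1.0 + clamp)
            stop("rd_integrate: solution left [0, 1] beyond clamp tolerance "
                 "(instability)");
          out(i, iout) = y[i];
        }
        ++iout;
        // resume from the controller's step, not the clipped remainder
        h = h * std::min(5.0, std::max(0.2, fac));
      } else {
        h = hs * std::min(5.0, std::max(0.2, fac));
      }
    } else {
      h = hs * std::max(0.1, fac);
    }
  }
  return out;
}
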