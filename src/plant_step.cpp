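#include <Rcpp.h>
using namespace Rcpp;

// Explicit finite-difference update of the Pennes bioheat equation on a
// regular 3-D grid with zero-flux (insulated) boundaries:
//
//   rho*c dT/dt = k lap(T) - rho*c * w * (T - Ta) + Q
//
// T is the temperature rise above baseline (degC), Q the deposited power
// density (W/m^3).  The replicated-edge Laplacian telescopes to zero over
// the domain, so with w = 0 the scheme conserves energy exactly (up to
// floating point) -- a property the test suite relies on.
//
// [[Rcpp::export(name = ".plant_step_cpp")]]
NumericVector plant_step_cpp(NumericVector temp, NumericVector q,
                             int nx, int ny, int nz,
                             double h, double k, double rc,
                             double perfusion, double arterial,
                             double dt, int nsub) {
  NumericVector A = clone(temp);
  NumericVector B(A.size());
  double *T = A.begin(), *Tn = B.begin();
  const double *Q = q.begin();
  const double a = dt * k / (rc * h * h);
  const double wdt = dt * perfusion;
  const double qscale = dt / rc;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int s = 0; s < nsub; ++s) {
    for (int l = 0; l < nz; ++l) {
      const R_xlen_t ozm = (l > 0 ? -sz : 0), ozp = (l < nz - 1 ? sz : 0);
      for (int j = 0; j < ny; ++j) {
        const R_xlen_t oym = (j > 0 ? -sy : 0), oyp = (j < ny - 1 ? sy : 0);
        const R_xlen_t row = sy * j + sz * l;
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t p = row + i;
          const R_xlen_t oxm = (i > 0 ? -sx : 0), oxp = (i < nx - 1 ? sx : 0);
          const double c = T[p];
          Tn[p] = c + a * (T[p + oxm] + T[p + oxp] + T[p + oym] + T[p + oyp] +
                           T[p + ozm] + T[p + ozp] - 6.0 * c)
                    - wdt * (c - arterial) + qscale * Q[p];
        }
      }
    }
    std::swap(T, Tn);
  }
  if (T == A.begin()) return A;
  return B;
}
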