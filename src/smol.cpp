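#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 1-D drift-diffusion stepper on a uniform cell-centered grid.
//
// Inter-cell flux between cells i and i+1 uses symmetric thermodynamic
// weighting (G in units of kBT enters through the precomputed face
// weights wl, wr):
//   j_{i+1/2} = -(D/dx) * ( wr[i]*u[i+1] - wl[i]*u[i] )
// with wl[i] = exp((G_i - G_{i+1})/2kBT), wr[i] = 1/wl[i]. This reduces
// to central-difference Fick flux for constant G and makes the Boltzmann
// distribution an exact stationary state with reflecting boundaries.

namespace {

struct Grid {
  int n;
  const double *wl, *wr;
  double r;          // D*dt/dx^2
  int boundary;      // 0 reflecting, 1 dirichlet (end cells pinned)
};

// One explicit (forward Euler) step.
inline void step_explicit(std::vector<double> &u, std::vector<double> &jf,
                          const Grid &g) {
  const int n = g.n;
  for (int i = 0; i < n - 1; ++i)
    jf[i] = g.wr[i] * u[i + 1] - g.wl[i] * u[i];
  if (g.boundary == 0) {            // reflecting: zero flux at outer faces
    u[0] += g.r * jf[0];
    for (int i = 1; i < n - 1; ++i) u[i] += g.r * (jf[i] - jf[i - 1]);
    u[n - 1] += g.r * (-jf[n - 2]);
  } else {                          // dirichlet: end cells held fixed
    for (int i = 1; i < n - 1; ++i) u[i] += g.r * (jf[i] - jf[i - 1]);
  }
}

// Precomputed Thomas factorization for the backward-Euler matrix
// M = I - dt*A (tridiagonal, constant in time).
struct Tridiag {
  std::vector<double> a, cp, inv_denom;  // a: sub-diagonal; cp: c'/denom
  int n;
  void build(const Grid &g) {
    n = g.n;
    std::vector<double> b(n), c(n);
    a.assign(n, 0.0);
    for (int i = 0; i < n; ++i) {
      double sub = 0, sup = 0, diag = 0;
      bool pinned = (g.boundary == 1) && (i == 0 || i == n - 1);
      if (pinned) {
        diag = 0;
      } else {
        if (i > 0)     { sub  = g.wl[i - 1]; diag -= g.wr[i - 1]; }
        if (i < n - 1) { sup  = g.wr[i];     diag -= g.wl[i]; }
      }
      a[i] = -g.r * sub;
      b[i] = 1.0 - g.r * diag;
      c[i] = -g.r * sup;
    }
    cp.assign(n, 0.0);
    inv_denom.assign(n, 0.0);
    double denom = b[0];
    inv_denom[0] = 1.0 / denom;
    cp[0] = c[0] * inv_denom[0];
    for (int i = 1; i < n; ++i) {
      denom = b[i] - a[i] * cp[i - 1];
      inv_denom[i] = 1.0 / denom;
      cp[i] = c[i] * inv_denom[i];
    }
  }
  void solve(std::vector<double> &u, std::vector<double> &dp) const {
    dp[0] = u[0] * inv_denom[0];
    for (int i = 1; i < n; ++i)
      dp[i] = (u[i] - a[i] * dp[i - 1]) * inv_denom[i];
    u[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) u[i] = dp[i] - cp[i] * u[i + 1];
  }
};

inline double face_flux(const std::vector<double> &u, const Grid &g,
                        double D_over_dx, int face) {
  return -D_over_dx * (g.wr[face] * u[face + 1] - g.wl[face] * u[face]);
}

} // namespace

// Run the stepper. If n_steps_target > 0, advance exactly that many steps
// (no convergence testing). Otherwise iterate up to max_steps, checking
// every check_interval steps for steady state: relative change of the
// outlet-face flux below steady_tol AND inlet/outlet flux agreement below
// flux_agree_tol.
// [[Rcpp::export]]
List smol_run_cpp(NumericVector u0, NumericVector wl, NumericVector wr,
                  double D, double dx, double dt,
                  int scheme, int boundary,
                  double n_steps_target, double max_steps,
                  int check_interval, double steady_tol,
                  double flux_agree_tol, int face_in, int face_out) {
  const int n = u0.size();
  if (wl.size() != n - 1 || wr.size() != n - 1)
    stop("face weight vectors must have length n-1");
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> scratch(n, 0.0);
  Grid g{n, wl.begin(), wr.begin(), D * dt / (dx * dx), boundary};
  Tridiag tri;
  if (scheme == 1) tri.build(g);
  const double D_over_dx = D / dx;

  double steps_done = 0.0;
  bool converged = false;
  double prev_flux = NA_REAL;
  double fi = NA_REAL, fo = NA_REAL;

  if (n_steps_target > 0) {
    for (double s = 0; s < n_steps_target; s += 1.0) {
      if (scheme == 0) step_explicit(u, scratch, g);
      else tri.solve(u, scratch);
    }
    steps_done = n_steps_target;
    fi = face_flux(u, g, D_over_dx, face_in);
    fo = face_flux(u, g, D_over_dx, face_out);
  } else {
    while (steps_done < max_steps) {
      double chunk = std::min((double)check_interval, max_steps - steps_done);
      for (double s = 0; s < chunk; s += 1.0) {
        if (scheme == 0) step_explicit(u, scratch, g);
        else tri.solve(u, scratch);
      }
      steps_done += chunk;
      fi = face_flux(u, g, D_over_dx, face_in);
      fo = face_flux(u, g, D_over_dx, face_out);
      if (!std::isfinite(fi) || !std::isfinite(fo))
        stop("non-finite flux after %.0f steps: the scheme is unstable "
             "(reduce dt or use the implicit scheme)", steps_done);
      if (R_finite(prev_flux)) {
        double scale = std::max(std::fabs(fo), 1e-300);
        double rel = std::fabs(fo - prev_flux) / scale;
        double agree = std::fabs(fi - fo) / scale;
        if (rel < steady_tol && agree < flux_agree_tol) {
          converged = true;
          break;
        }
      }
      prev_flux = fo;
      Rcpp::checkUserInterrupt();
    }
  }
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(u[i]))
      stop("non-finite concentration after %.0f steps", steps_done);

  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["steps"] = steps_done,
                      _["flux_in"] = fi, _["flux_out"] = fo,
                      _["converged"] = converged);
}
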