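#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Implicit (backward-Euler) finite-volume stepping of the Pennes bioheat
// equation on a regular voxel grid:
//
//   rho*c dT/dt = div( lambda(T) grad T ) + w(Omega)*(Tb - T) + Qmet + Q
//
// with w = rho_b*c_b*omega_b(Omega) (W m^-3 K^-1). lambda(T) and
// omega_b(Omega) are lagged one step, so every step solves a symmetric
// positive-definite linear system; it is solved matrix-free with
// Jacobi-preconditioned conjugate gradients (warm-started from the previous
// temperature field). Face conductivities use harmonic means so heat flux is
// continuous across the seed-tissue interface. Boundary conditions are per
// outer face: Dirichlet (fixed T at the face, half-cell flux), Neumann
// (insulated) or Robin (convective, h and T_amb).
//
// Face order throughout: 0 = x-lo, 1 = x-hi, 2 = y-lo, 3 = y-hi,
//                        4 = z-lo, 5 = z-hi.

static inline double perfusion_multiplier(double om) {
  if (om <= 0.0) return 1.0;
  if (om <= 0.1) return 1.0 + 25.0 * om - 260.0 * om * om;
  if (om <= 1.0) return 1.0 - om;
  return 0.0;
}

struct StencilOp {
  int nx, ny, nz, nvox;
  double h;
  // face conductances (lambda_harm / h^2), defined between voxel i and its
  // +x / +y / +z neighbour; entries on the high boundary are unused (0)
  std::vector<double> cx, cy, cz;
  std::vector<double> diag;   // full diagonal incl. mass, perfusion, BC terms

  StencilOp(int nx_, int ny_, int nz_, double h_)
    : nx(nx_), ny(ny_), nz(nz_), nvox(nx_ * ny_ * nz_), h(h_),
      cx(nvox, 0.0), cy(nvox, 0.0), cz(nvox, 0.0), diag(nvox, 0.0) {}

  inline int id(int i, int j, int k) const { return i + nx * (j + ny * k); }

  // y = A x
  void apply(const std::vector<double>& x, std::vector<double>& y) const {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const int base = nx * (j + ny * k);
        for (int i = 0; i < nx; ++i) {
          const int p = base + i;
          double v = diag[p] * x[p];
          if (i > 0)      v -= cx[p - 1]       * x[p - 1];
          if (i < nx - 1) v -= cx[p]           * x[p + 1];
          if (j > 0)      v -= cy[p - nx]      * x[p - nx];
          if (j < ny - 1) v -= cy[p]           * x[p + nx];
          if (k > 0)      v -= cz[p - nx * ny] * x[p - nx * ny];
          if (k < nz - 1) v -= cz[p]           * x[p + nx * ny];
          y[p] = v;
        }
      }
  }
};

// Jacobi-preconditioned CG; returns iterations used (-1 on failure).
static int pcg_solve(const StencilOp& A, const std::vector<double>& b,
                     std::vector<double>& x, double rtol, int maxit) {
  const int n = A.nvox;
  std::vector<double> r(n), z(n), p(n), Ap(n);
  A.apply(x, Ap);
  double bnorm2 = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = b[i] - Ap[i];
    bnorm2 += b[i] * b[i];
  }
  const double tol2 = rtol * rtol * (bnorm2 > 0.0 ? bnorm2 : 1.0);
  double rz = 0.0;
  for (int i = 0; i < n; ++i) {
    z[i] = r[i] / A.diag[i];
    rz += r[i] * z[i];
    p[i] = z[i];
  }
  double rnorm2 = 0.0;
  for (int i = 0; i < n; ++i) rnorm2 += r[i] * r[i];
  if (rnorm2 <= tol2) return 0;
  for (int it = 1; it <= maxit; ++it) {
    A.apply(p, Ap);
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0.0) return -1;  // not SPD: coding error upstream
    const double alpha = rz / pAp;
    rnorm2 = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rnorm2 += r[i] * r[i];
    }
    if (rnorm2 <= tol2) return it;
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) {
      z[i] = r[i] / A.diag[i];
      rz_new += r[i] * z[i];
    }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }
  return -1;
}

static inline double harm(double a, double b) {
  const double s = a + b;
  return s > 0.0 ? 2.0 * a * b / s : 0.0;
}

// [[Rcpp::export(name = ".bioheat_step_cpp")]]
List bioheat_solve_cpp(IntegerVector dims, double h,
                       NumericVector rho_c,      // J m^-3 K^-1, per voxel
                       NumericVector lambda37,   // W m^-1 K^-1, per voxel
                       NumericVector perf0,      // rho_b*c_b*omega_b0, W m^-3 K^-1
                       NumericVector qmet,       // W m^-3
                       NumericVector qext,       // W m^-3
                       NumericVector T_init,     // K
                       double dt, int nsteps, double Tb,
                       IntegerVector bc_kind,    // length 6: 0 Dirichlet, 1 Neumann, 2 Robin
                       NumericVector bc_Tfix,    // K, per face
                       NumericVector bc_hcoef,   // W m^-2 K^-1, per face
                       NumericVector bc_Tamb,    // K, per face
                       double lam_coeff, double lam_Tref, double lam_floor,
                       double arr_A, double arr_Ea, double arr_R,
                       bool two_way,
                       IntegerVector probe_idx,  // 0-based flat voxel indices
                       int snap_every,           // steps; <= 0 -> final only
                       double cg_rtol, int cg_maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  if (rho_c.size() != nvox || lambda37.size() != nvox || T_init.size() != nvox)
    stop("field length does not match grid dimensions");

  StencilOp A(nx, ny, nz, h);
  const double h2 = h * h;
  const double log_arr_A = std::log(arr_A);

  std::vector<double> T(T_init.begin(), T_init.end());
  std::vector<double> T_old(nvox), Omega(nvox, 0.0), lam(nvox), perf(nvox);
  std::vector<double> b(nvox), bc_diag(nvox), bc_rhs(nvox);

  const int nprobe = probe_idx.size();
  NumericMatrix probe_T(nsteps + 1, nprobe), probe_Om(nsteps + 1, nprobe);
  for (int q = 0; q < nprobe; ++q) {
    probe_T(0, q) = T[probe_idx[q]];
    probe_Om(0, q) = 0.0;
  }

  // snapshot bookkeeping
  std::vector<int> snap_steps;
  if (snap_every > 0)
    for (int s = snap_every; s < nsteps; s += snap_every) snap_steps.push_back(s);
  snap_steps.push_back(nsteps);
  const int nsnap = (int) snap_steps.size();
  NumericMatrix snap_T(nvox, nsnap), snap_Om(nvox, nsnap);
  NumericVector snap_time(nsnap);

  NumericVector energy_resid(nsteps), cg_iters(nsteps);
  bool lam_clamped = false;

  int isnap = 0;
  for (int step = 1; step <= nsteps; ++step) {
    std::swap(T, T_old);
    T = T_old;  // warm start

    // lagged nonlinearities
    for (int p = 0; p < nvox; ++p) {
      double l = lambda37[p] * (1.0 + lam_coeff * (T_old[p] - lam_Tref));
      if (l < lam_floor) { l = lam_floor; lam_clamped = true; }
      lam[p] = l;
      perf[p] = perf0[p] * perfusion_multiplier(two_way ? Omega[p] : 0.0);
    }

    // face conductances
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int p = A.id(i, j, k);
          A.cx[p] = (i < nx - 1) ? harm(lam[p], lam[p + 1]) / h2 : 0.0;
          A.cy[p] = (j < ny - 1) ? harm(lam[p], lam[p + nx]) / h2 : 0.0;
          A.cz[p] = (k < nz - 1) ? harm(lam[p], lam[p + nx * ny]) / h2 : 0.0;
        }

    // boundary contributions (depend on lam, so rebuilt every step)
    std::fill(bc_diag.begin(), bc_diag.end(), 0.0);
    std::fill(bc_rhs.begin(), bc_rhs.end(), 0.0);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
            continue;
          const int p = A.id(i, j, k);
          int faces[6];
          int nf = 0;
          if (i == 0)      faces[nf++] = 0;
          if (i == nx - 1) faces[nf++] = 1;
          if (j == 0)      faces[nf++] = 2;
          if (j == ny - 1) faces[nf++] = 3;
          if (k == 0)      faces[nf++] = 4;
          if (k == nz - 1) faces[nf++] = 5;
          for (int f = 0; f < nf; ++f) {
            const int face = faces[f];
            if (bc_kind[face] == 0) {            // Dirichlet at half-cell
              const double c = 2.0 * lam[p] / h2;
              bc_diag[p] += c;
              bc_rhs[p] += c * bc_Tfix[face];
            } else if (bc_kind[face] == 2) {     // Robin
              const double c = bc_hcoef[face] / h;
              bc_diag[p] += c;
              bc_rhs[p] += c * bc_Tamb[face];
            }                                     // Neumann: nothing
          }
        }

    // assemble diagonal and rhs
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int p = A.id(i, j, k);
          double d = rho_c[p] / dt + perf[p] + bc_diag[p];
          if (i > 0)      d += A.cx[p - 1];
          if (i < nx - 1) d += A.cx[p];
          if (j > 0)      d += A.cy[p - nx];
          if (j < ny - 1) d += A.cy[p];
          if (k > 0)      d += A.cz[p - nx * ny];
          if (k < nz - 1) d += A.cz[p];
          A.diag[p] = d;
          b[p] = rho_c[p] / dt * T_old[p] + perf[p] * Tb + qmet[p] + qext[p]
               + bc_rhs[p];
        }

    const int its = pcg_solve(A, b, T, cg_rtol, cg_maxit);
    if (its < 0) stop("conjugate-gradient solve failed at step %d", step);
    cg_iters[step - 1] = its;
    for (int p = 0; p < nvox; ++p)
      if (!std::isfinite(T[p]))
        stop("non-finite temperature at step %d (voxel %d)", step, p + 1);

    // global energy balance of the step, assembled independently from the
    // linear system: d/dt sum(rho*c*T) V  vs  sources + perfusion + boundary
    // flux, all evaluated at T_new (backward Euler). Interior face fluxes
    // cancel by construction; any mismatch is solver error.
    {
      double dEdt = 0.0, rhs = 0.0, gross = 0.0;
      for (int p = 0; p < nvox; ++p) {
        dEdt += rho_c[p] * (T[p] - T_old[p]) / dt;
        const double perf_term = perf[p] * (Tb - T[p]);
        const double bc_term = bc_rhs[p] - bc_diag[p] * T[p];
        rhs += perf_term + qmet[p] + qext[p] + bc_term;
        gross += std::abs(perf_term) + qmet[p] + std::abs(qext[p])
               + std::abs(bc_term);
      }
      // normalised by the gross energy flow so a near-steady state does not
      // divide zero by zero
      const double scale = std::max(std::abs(dEdt), gross);
      energy_resid[step - 1] =
        scale > 0.0 ? std::abs(dEdt - rhs) / scale : 0.0;
    }

    // Arrhenius damage, trapezoidal in time (always accumulated; feeds the
    // perfusion only in two-way mode)
    for (int p = 0; p < nvox; ++p) {
      const double k1 = std::exp(log_arr_A - arr_Ea / (arr_R * T_old[p]));
      const double k2 = std::exp(log_arr_A - arr_Ea / (arr_R * T[p]));
      Omega[p] += 0.5 * dt * (k1 + k2);
    }

    for (int q = 0; q < nprobe; ++q) {
      probe_T(step, q) = T[probe_idx[q]];
      probe_Om(step, q) = Omega[probe_idx[q]];
    }

    if (isnap < nsnap && step == snap_steps[isnap]) {
      for (int p = 0; p < nvox; ++p) {
        snap_T(p, isnap) = T[p];
        snap_Om(p, isnap) = Omega[p];
      }
      snap_time[isnap] = step * dt;
      ++isnap;
    }
  }

  return List::create(
    _["snap_time"] = snap_time,
    _["snap_T"] = snap_T,
    _["snap_Omega"] = snap_Om,
    _["probe_T"] = probe_T,
    _["probe_Omega"] = probe_Om,
    _["energy_resid"] = energy_resid,
    _["cg_iters"] = cg_iters,
    _["lambda_clamped"] = lam_clamped);
}
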