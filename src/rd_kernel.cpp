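#include <Rcpp.h>
#include <cmath>
#include <vector>

// Backward-Euler Newton stepping of the tumor reaction-diffusion equation
//   dN/dt = div(D grad N) + rho N (1 - N/theta)
// on a structured voxel grid with zero-flux boundaries. The diffusion
// operator is the conservative 7-point stencil with face-averaged
// diffusivities (passed in already divided by the squared spacing), so the
// total mass change over a step is exactly the integrated reaction term.

namespace {

struct GridDims {
  int nx, ny, nz, n;
};

// y = L x with L the conservative flux Laplacian
void apply_lap(const GridDims &g, const double *x, const double *dfx,
               const double *dfy, const double *dfz, double *y) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  std::fill(y, y + g.n, 0.0);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const int base = nx * (j + ny * k);
      const int fbase = (nx - 1) * (j + ny * k);
      for (int i = 0; i < nx - 1; ++i) {
        const double flux = dfx[fbase + i] * (x[base + i + 1] - x[base + i]);
        y[base + i] += flux;
        y[base + i + 1] -= flux;
      }
    }
  }
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      const int base = nx * (j + ny * k);
      const int fbase = nx * (j + (ny - 1) * k);
      for (int i = 0; i < nx; ++i) {
        const double flux = dfy[fbase + i] * (x[base + nx + i] - x[base + i]);
        y[base + i] += flux;
        y[base + nx + i] -= flux;
      }
    }
  }
  const int nxy = nx * ny;
  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny; ++j) {
      const int base = nx * (j + ny * k);
      for (int i = 0; i < nx; ++i) {
        const double flux = dfz[base + i] * (x[base + nxy + i] - x[base + i]);
        y[base + i] += flux;
        y[base + nxy + i] -= flux;
      }
    }
  }
}

// diagonal of -L (positive)
void lap_diag(const GridDims &g, const double *dfx, const double *dfy,
              const double *dfz, double *diag) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  std::fill(diag, diag + g.n, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const int base = nx * (j + ny * k);
      const int fbase = (nx - 1) * (j + ny * k);
      for (int i = 0; i < nx - 1; ++i) {
        diag[base + i] += dfx[fbase + i];
        diag[base + i + 1] += dfx[fbase + i];
      }
    }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny - 1; ++j) {
      const int base = nx * (j + ny * k);
      const int fbase = nx * (j + (ny - 1) * k);
      for (int i = 0; i < nx; ++i) {
        diag[base + i] += dfy[fbase + i];
        diag[base + nx + i] += dfy[fbase + i];
      }
    }
  const int nxy = nx * ny;
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny; ++j) {
      const int base = nx * (j + ny * k);
      for (int i = 0; i < nx; ++i) {
        diag[base + i] += dfz[base + i];
        diag[base + nxy + i] += dfz[base + i];
      }
    }
}

struct Work {
  std::vector<double> F, d, q, z, r, lapv, ldiag;
  void resize(int n) {
    F.resize(n); d.resize(n); q.resize(n); z.resize(n); r.resize(n);
    lapv.resize(n); ldiag.resize(n);
  }
};

// One implicit (backward Euler) step for a single run. N is updated in
// place. Returns the number of Newton iterations; throws on failure.
//
// The Newton iteration starts from a forward-Euler predictor and solves
// each linear system inexactly (Jacobi-preconditioned CG with forcing
// term 1e-4); the outer residual check still enforces the full relative
// tolerance, so the inexact inner solves only affect the iteration count.
int newton_step(const GridDims &g, double *N, const double *rho,
                const double *dfx, const double *dfy, const double *dfz,
                double dt, double theta, double rtol, int max_newton,
                Work &w, long long *clip_count, long long *cg_count) {
  const int n = g.n;
  lap_diag(g, dfx, dfy, dfz, w.ldiag.data());
  std::vector<double> Nnew(N, N + n);
  double scale = 0.0;
  for (int v = 0; v < n; ++v) scale += N[v] * N[v];
  scale = std::sqrt(scale);
  if (scale <= 0.0) scale = theta * 1e-12;

  // forward-Euler predictor
  apply_lap(g, Nnew.data(), dfx, dfy, dfz, w.lapv.data());
  for (int v = 0; v < n; ++v) {
    Nnew[v] += dt * (w.lapv[v] + rho[v] * Nnew[v] * (1.0 - Nnew[v] / theta));
  }

  std::vector<double> c(n), delta(n);
  int it = 0;
  for (; it < max_newton; ++it) {
    // residual F = Nnew - N - dt (L Nnew + rho Nnew (1 - Nnew/theta))
    apply_lap(g, Nnew.data(), dfx, dfy, dfz, w.lapv.data());
    double fn = 0.0;
    for (int v = 0; v < n; ++v) {
      const double react = rho[v] * Nnew[v] * (1.0 - Nnew[v] / theta);
      w.F[v] = Nnew[v] - N[v] - dt * (w.lapv[v] + react);
      fn += w.F[v] * w.F[v];
    }
    fn = std::sqrt(fn);
    if (fn <= rtol * scale) break;

    // Jacobian J = I - dt L - dt diag(rho (1 - 2 Nnew/theta));
    // solve J delta = -F by Jacobi-preconditioned CG
    for (int v = 0; v < n; ++v)
      c[v] = 1.0 - dt * rho[v] * (1.0 - 2.0 * Nnew[v] / theta);
    std::fill(delta.begin(), delta.end(), 0.0);
    double rz = 0.0, rhs_norm2 = 0.0;
    for (int v = 0; v < n; ++v) {
      w.r[v] = -w.F[v];
      const double m = c[v] + dt * w.ldiag[v];
      w.z[v] = w.r[v] / (m > 1e-300 ? m : 1.0);
      w.d[v] = w.z[v];
      rz += w.r[v] * w.z[v];
      rhs_norm2 += w.r[v] * w.r[v];
    }
    const double cg_tol2 = 1e-8 * rhs_norm2; // forcing term 1e-4 (squared)
    const int max_cg = 500;
    int cg = 0;
    for (; cg < max_cg; ++cg) {
      apply_lap(g, w.d.data(), dfx, dfy, dfz, w.lapv.data());
      double dq = 0.0;
      for (int v = 0; v < n; ++v) {
        w.q[v] = c[v] * w.d[v] - dt * w.lapv[v];
        dq += w.d[v] * w.q[v];
      }
      if (dq <= 0.0)
        Rcpp::stop("implicit solver: indefinite Jacobian encountered");
      const double alpha = rz / dq;
      double rn = 0.0;
      for (int v = 0; v < n; ++v) {
        delta[v] += alpha * w.d[v];
        w.r[v] -= alpha * w.q[v];
        rn += w.r[v] * w.r[v];
      }
      if (rn <= cg_tol2) { ++cg; break; }
      double rz_new = 0.0;
      for (int v = 0; v < n; ++v) {
        const double m = c[v] + dt * w.ldiag[v];
        w.z[v] = w.r[v] / (m > 1e-300 ? m : 1.0);
        rz_new += w.r[v] * w.z[v];
      }
      const double bfac = rz_new / rz;
      rz = rz_new;
      for (int v = 0; v < n; ++v) w.d[v] = w.z[v] + bfac * w.d[v];
    }
    if (cg_count) *cg_count += cg;
    for (int v = 0; v < n; ++v) Nnew[v] += delta[v];
  }
  if (it == max_newton)
    Rcpp::stop("implicit solver: Newton did not converge in %d iterations",
               max_newton);

  // bound diagnostics: zero tiny undershoots, clip tiny overshoots
  const double tol_abs = 1e-10 * theta;
  for (int v = 0; v < n; ++v) {
    if (Nnew[v] < 0.0) {
      if (Nnew[v] < -tol_abs)
        Rcpp::stop("density undershoot %.3e below zero exceeds tolerance",
                   Nnew[v]);
      Nnew[v] = 0.0;
      ++(*clip_count);
    } else if (Nnew[v] > theta) {
      if (Nnew[v] > theta + tol_abs)
        Rcpp::stop("density overshoot %.3e above theta exceeds tolerance",
                   Nnew[v] - theta);
      Nnew[v] = theta;
      ++(*clip_count);
    }
  }
  std::copy(Nnew.begin(), Nnew.end(), N);
  return it + 1;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List rd_step_cpp(Rcpp::NumericVector N, Rcpp::IntegerVector dims,
                       Rcpp::NumericVector dfx, Rcpp::NumericVector dfy,
                       Rcpp::NumericVector dfz, Rcpp::NumericVector rho,
                       double dt, double theta, double rtol, int max_newton) {
  GridDims g{dims[0], dims[1], dims[2], dims[0] * dims[1] * dims[2]};
  if (N.size() != g.n || rho.size() != g.n)
    Rcpp::stop("field length does not match grid dims");
  Rcpp::NumericVector out = Rcpp::clone(N);
  Work w;
  w.resize(g.n);
  long long clips = 0;
  long long cg = 0;
  int iters = newton_step(g, out.begin(), rho.begin(), dfx.begin(),
                          dfy.begin(), dfz.begin(), dt, theta, rtol,
                          max_newton, w, &clips, &cg);
  return Rcpp::List::create(Rcpp::Named("N") = out,
                            Rcpp::Named("newton_iters") = iters,
                            Rcpp::Named("clip_count") = (double)clips);
}

// Advance a chunk of independent runs over `nsteps` implicit steps. The
// stress state is frozen over the block: the von Mises field sv (n x m)
// and per-run baseline diffusivity D0 give D = D0 exp(-gammaN sv), whose
// face averages (divided by the squared spacing) feed the conservative
// stencil. The per-run, per-step proliferation-rate fields come in
// separable MuSyC form: rho(x) = (sum_k a_k Q_k(x)) / (sum_k b_k Q_k(x))
// with monomial basis Q = {1, P1, P2, P1^2, P2^2, P1 P2, P1^2 P2,
// P1 P2^2} built from the static fields P1 = p^h1, P2 = p^h2. coefs has
// dim (16, nsteps, m): rows 1..8 numerator (rho0 included), 9..16
// denominator. Returns final densities plus per-step tumor volume and
// total cell count; with keep_all the full density history (n, m, nsteps)
// is included.
// [[Rcpp::export]]
Rcpp::List advance_block_cpp(
    Rcpp::NumericMatrix N, Rcpp::IntegerVector dims,
    Rcpp::NumericMatrix sv, Rcpp::NumericVector D0, double gammaN,
    Rcpp::NumericVector spacing,
    Rcpp::NumericMatrix P1, Rcpp::NumericMatrix P2,
    Rcpp::NumericVector coefs, int nsteps, double dt, double theta,
    double rtol, int max_newton, double nth, double voxvol, bool keep_all) {
  GridDims g{dims[0], dims[1], dims[2], dims[0] * dims[1] * dims[2]};
  const int nx = g.nx, ny = g.ny, nz = g.nz, n = g.n;
  const int m = N.ncol();
  if (N.nrow() != n || sv.nrow() != n)
    Rcpp::stop("field length does not match grid dims");
  if (coefs.size() != 16 * (R_xlen_t)nsteps * m)
    Rcpp::stop("coefficient array size mismatch");
  Rcpp::NumericMatrix Nout(n, m);
  Rcpp::NumericMatrix VT(nsteps, m), NT(nsteps, m);
  Rcpp::NumericVector all;
  if (keep_all) all = Rcpp::NumericVector(Rcpp::Dimension(n, m, nsteps));
  Work w;
  w.resize(n);
  std::vector<double> rho(n), Ncur(n), Dv(n);
  std::vector<double> dfx((nx - 1) * ny * nz), dfy(nx * (ny - 1) * nz),
      dfz(nx * ny * (nz - 1));
  const double ihx2 = 1.0 / (spacing[0] * spacing[0]);
  const double ihy2 = 1.0 / (spacing[1] * spacing[1]);
  const double ihz2 = 1.0 / (spacing[2] * spacing[2]);
  const int nxy = nx * ny;
  long long clips = 0, newton_total = 0, cg_total = 0;
  for (int r = 0; r < m; ++r) {
    std::copy(N.column(r).begin(), N.column(r).end(), Ncur.begin());
    const double *svr = &sv(0, r);
    for (int v = 0; v < n; ++v) Dv[v] = D0[r] * std::exp(-gammaN * svr[v]);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const int base = nx * (j + ny * k);
        const int fbase = (nx - 1) * (j + ny * k);
        for (int i = 0; i < nx - 1; ++i)
          dfx[fbase + i] = 0.5 * (Dv[base + i] + Dv[base + i + 1]) * ihx2;
      }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny - 1; ++j) {
        const int base = nx * (j + ny * k);
        const int fbase = nx * (j + (ny - 1) * k);
        for (int i = 0; i < nx; ++i)
          dfy[fbase + i] = 0.5 * (Dv[base + i] + Dv[base + nx + i]) * ihy2;
      }
    for (int k = 0; k < nz - 1; ++k)
      for (int j = 0; j < ny; ++j) {
        const int base = nx * (j + ny * k);
        for (int i = 0; i < nx; ++i)
          dfz[base + i] = 0.5 * (Dv[base + i] + Dv[base + nxy + i]) * ihz2;
      }
    const double *p1 = &P1(0, r);
    const double *p2 = &P2(0, r);
    for (int s = 0; s < nsteps; ++s) {
      const double *cf = &coefs[16 * ((R_xlen_t)s + (R_xlen_t)nsteps * r)];
      for (int v = 0; v < n; ++v) {
        const double q1 = p1[v], q2 = p2[v];
        const double q11 = q1 * q1, q22 = q2 * q2, q12 = q1 * q2;
        const double num = cf[0] + cf[1] * q1 + cf[2] * q2 + cf[3] * q11 +
                           cf[4] * q22 + cf[5] * q12 + cf[6] * q11 * q2 +
                           cf[7] * q1 * q22;
        const double den = cf[8] + cf[9] * q1 + cf[10] * q2 + cf[11] * q11 +
                           cf[12] * q22 + cf[13] * q12 + cf[14] * q11 * q2 +
                           cf[15] * q1 * q22;
        rho[v] = num / den;
      }
      newton_total += newton_step(g, Ncur.data(), rho.data(), dfx.data(),
                                  dfy.data(), dfz.data(), dt, theta, rtol,
                                  max_newton, w, &clips, &cg_total);
      double vt = 0.0, nt = 0.0;
      for (int v = 0; v < n; ++v) {
        if (Ncur[v] >= nth) vt += 1.0;
        nt += Ncur[v];
      }
      VT(s, r) = vt * voxvol;
      NT(s, r) = nt * voxvol;
      if (keep_all)
        std::copy(Ncur.begin(), Ncur.end(),
                  &all[(R_xlen_t)n * (r + (R_xlen_t)m * s)]);
    }
    std::copy(Ncur.begin(), Ncur.end(), Nout.column(r).begin());
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("N") = Nout, Rcpp::Named("VT") = VT,
      Rcpp::Named("NT") = NT, Rcpp::Named("clip_count") = (double)clips,
      Rcpp::Named("newton_total") = (double)newton_total,
      Rcpp::Named("cg_total") = (double)cg_total);
  if (keep_all) out["all"] = all;
  return out;
}

// Von Mises stress recovery from the displacement solution of a chunk of
// runs. U is the 3n x m displacement matrix with dofs interleaved per node
// (x, y, z); Nmat the n x m density matrix. Gradients use central
// differences in the interior and one-sided differences on the box faces,
// matching the R-level stress recovery exactly. Returns the n x m von
// Mises field.
// [[Rcpp::export]]
Rcpp::NumericMatrix von_mises_u_cpp(Rcpp::NumericMatrix U,
                                    Rcpp::NumericMatrix Nmat,
                                    Rcpp::IntegerVector dims,
                                    Rcpp::NumericVector spacing,
                                    double lambda, double mu,
                                    double g_over_theta) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int m = Nmat.ncol();
  if (U.nrow() != 3 * n || Nmat.nrow() != n)
    Rcpp::stop("displacement/density shapes do not match grid dims");
  Rcpp::NumericMatrix out(n, m);
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const int nxy = nx * ny;
  for (int r = 0; r < m; ++r) {
    const double *u = &U(0, r);
    const double *Nv = &Nmat(0, r);
    double *sv = &out(0, r);
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int v = i + nx * j + nxy * k;
          // derivative of component c at node v along axis a
          auto deriv = [&](int c, int a) {
            int stride, idx = v, lim, pos;
            double h;
            if (a == 0) { stride = 1; pos = i; lim = nx; h = hx; }
            else if (a == 1) { stride = nx; pos = j; lim = ny; h = hy; }
            else { stride = nxy; pos = k; lim = nz; h = hz; }
            if (pos == 0)
              return (u[3 * (idx + stride) + c] - u[3 * idx + c]) / h;
            if (pos == lim - 1)
              return (u[3 * idx + c] - u[3 * (idx - stride) + c]) / h;
            return (u[3 * (idx + stride) + c] - u[3 * (idx - stride) + c]) /
                   (2.0 * h);
          };
          const double dxx = deriv(0, 0), dyy = deriv(1, 1), dzz = deriv(2, 2);
          const double div = dxx + dyy + dzz;
          const double growth = g_over_theta * Nv[v];
          const double s11 = lambda * div + 2.0 * mu * dxx - growth;
          const double s22 = lambda * div + 2.0 * mu * dyy - growth;
          const double s33 = lambda * div + 2.0 * mu * dzz - growth;
          const double s12 = mu * (deriv(0, 1) + deriv(1, 0));
          const double s23 = mu * (deriv(1, 2) + deriv(2, 1));
          const double s13 = mu * (deriv(0, 2) + deriv(2, 0));
          double val = s11 * s11 + s22 * s22 + s33 * s33 -
                       s11 * s22 - s22 * s33 - s11 * s33 +
                       3.0 * (s12 * s12 + s23 * s23 + s13 * s13);
          sv[v] = val > 0.0 ? std::sqrt(val) : 0.0;
        }
      }
    }
  }
  return out;
}
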