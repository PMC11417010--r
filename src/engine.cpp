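#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <R_ext/BLAS.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Deterministic expected-SFS engine: moment equations for the sample site
// frequency spectrum under neutral drift, size change, mutation influx and
// migration, in the Bernstein-moment basis. Drift is closed at the tracked
// sample size (tridiagonal operator, Crank-Nicolson); migration requires
// order n+1 moments and is closed with a local-interpolation jackknife
// supplied from R as dense matrices.
//
// Time in units of 2*Ne_anc generations; sizes nu relative to Ne_anc;
// migration M = 2*Ne_anc*m (forward convention: M_1to2 moves genes 1 -> 2,
// so the equation for population 2 carries M_1to2). theta = 4*Ne_anc*mu*L.
//
// Epoch matrix layout matches coalescent.cpp (rows oldest -> newest).

static double nu_fwd(double f, double nus, double nue, int dyn) {
  // f in [0,1]: forward fraction through the epoch
  if (dyn == 0) return nue;
  if (dyn == 1) return nus + (nue - nus) * f;
  return nus * std::pow(nue / nus, f);
}

// Crank-Nicolson drift substep of duration h at size nu on a length-(n+1)
// vector (in place). influx adds dt * b at index 1 (singletons) when b > 0.
static void cn_drift_1d(std::vector<double>& phi, int n, double h, double nu, double b) {
  int m = n + 1;
  double c = h / (4.0 * nu);
  // tridiagonal coefficients of D: row i gets sub*phi[i-1] + dia*phi[i] + sup*phi[i+1]
  static thread_local std::vector<double> lo, di, up, rhs;
  lo.resize(m); di.resize(m); up.resize(m); rhs.resize(m);
  for (int i = 0; i < m; ++i) {
    double sub = (i >= 1) ? (double)(i - 1) * (n - i + 1) : 0.0;
    double dia = -2.0 * i * (n - i);
    double sup = (i < n) ? (double)(i + 1) * (n - i - 1) : 0.0;
    double r = phi[i] + c * (sub * (i >= 1 ? phi[i - 1] : 0.0) + dia * phi[i] + sup * (i < n ? phi[i + 1] : 0.0));
    rhs[i] = r;
    lo[i] = -c * sub; di[i] = 1.0 - c * dia; up[i] = -c * sup;
  }
  if (b > 0.0) rhs[1] += h * b;
  // Thomas algorithm
  for (int i = 1; i < m; ++i) {
    double w = lo[i] / di[i - 1];
    di[i] -= w * up[i - 1];
    rhs[i] -= w * rhs[i - 1];
  }
  phi[m - 1] = rhs[m - 1] / di[m - 1];
  for (int i = m - 2; i >= 0; --i) phi[i] = (rhs[i] - up[i] * phi[i + 1]) / di[i];
}

// Crank-Nicolson drift applied along one axis of a 2-D grid: the tridiagonal
// factorization depends only on (n, h, nu), so it is computed once and reused
// for every row/column. influx b feeds the singleton of the lane with the
// other population monomorphic at zero (lane index 0).
struct AxisCN {
  int n;
  std::vector<double> lo, di, up, w, rhs;
  void setup(int n_, double h, double nu) {
    n = n_;
    int m = n + 1;
    lo.resize(m); di.resize(m); up.resize(m); w.resize(m); rhs.resize(m);
    double c = h / (4.0 * nu);
    for (int i = 0; i < m; ++i) {
      double sub = (i >= 1) ? (double)(i - 1) * (n - i + 1) : 0.0;
      double dia = -2.0 * i * (n - i);
      double sup = (i < n) ? (double)(i + 1) * (n - i - 1) : 0.0;
      lo[i] = -c * sub; di[i] = 1.0 - c * dia; up[i] = -c * sup;
    }
    for (int i = 1; i < m; ++i) { // in-place LU of the tridiagonal
      w[i] = lo[i] / di[i - 1];
      di[i] -= w[i] * up[i - 1];
    }
    cfac = c;
  }
  double cfac;
  // solve one lane in place; add h*b at index 1 (before the solve) if b > 0
  void lane(double* x, int stride, double h, double b) {
    int m = n + 1;
    double c = cfac;
    for (int i = 0; i < m; ++i) {
      double sub = (i >= 1) ? (double)(i - 1) * (n - i + 1) : 0.0;
      double dia = -2.0 * i * (n - i);
      double sup = (i < n) ? (double)(i + 1) * (n - i - 1) : 0.0;
      rhs[i] = x[i * stride] + c * (sub * (i >= 1 ? x[(i - 1) * stride] : 0.0)
                                    + dia * x[i * stride]
                                    + sup * (i < n ? x[(i + 1) * stride] : 0.0));
    }
    if (b > 0.0) rhs[1] += h * b;
    for (int i = 1; i < m; ++i) rhs[i] -= w[i] * rhs[i - 1];
    x[n * stride] = rhs[n] / di[n];
    for (int i = m - 2; i >= 0; --i)
      x[i * stride] = (rhs[i] - up[i] * x[(i + 1) * stride]) / di[i];
  }
};

// [[Rcpp::export(name = ".sfs_1d_engine_cpp")]]
NumericVector sfs_1d_engine_cpp(int n, NumericMatrix ep, double theta,
                                double dt_fac, int max_steps) {
  std::vector<double> phi(n + 1, 0.0);
  for (int i = 1; i < n; ++i) phi[i] = theta / i; // standard-neutral equilibrium
  double b = n * theta / 2.0;
  for (int r = 0; r < ep.nrow(); ++r) {
    double T = ep(r, 0);
    double nus = ep(r, 2), nue = ep(r, 3);
    int dyn = (int)ep(r, 4);
    double numin = (dyn == 0) ? nue : std::min(nus, nue);
    double dt = std::min(T / 50.0, dt_fac * 4.0 * numin / ((double)n * n));
    int steps = (int)std::ceil(T / dt);
    if (steps > max_steps) steps = max_steps;
    if (steps < 1) steps = 1;
    double h = T / steps;
    for (int s = 0; s < steps; ++s) {
      double f = (s + 0.5) / steps;
      cn_drift_1d(phi, n, h, nu_fwd(f, nus, nue, dyn), b);
    }
  }
  return NumericVector(phi.begin(), phi.end());
}

struct Grid {
  int n1, n2;
  std::vector<double> v; // (n1+1) x (n2+1), column-major in j
  double& at(int i, int j) { return v[i + (n1 + 1) * j]; }
  double get(int i, int j) const {
    if (i < 0 || j < 0 || i > n1 || j > n2) return 0.0;
    return v[i + (n1 + 1) * j];
  }
};

// psi = P %*% phi %*% t(J): P is (n1) x (n1+1) downsampling of axis 1,
// J is (n2+2) x (n2+1) jackknife on axis 2 (for the pop-1 migration term).
static void mig_terms(const Grid& phi,
                      const NumericMatrix& P1, const NumericMatrix& J2,
                      const NumericMatrix& P2, const NumericMatrix& J1,
                      double Min1, double Min2, std::vector<double>& out) {
  int n1 = phi.n1, n2 = phi.n2;
  std::fill(out.begin(), out.end(), 0.0);
  const double* pv = phi.v.data();
  if (Min1 > 0.0) {
    // Psi(a, b) with a = 0..n1-1 (size n1-1 spectrum), b = 0..n2+1 (size n2+1)
    static thread_local std::vector<double> tmp, psi;
    tmp.assign(n1 * (n2 + 1), 0.0); // P1 %*% phi
    const double* P1p = P1.begin(); int ld1 = P1.nrow();
    for (int j = 0; j <= n2; ++j) {
      const double* col = pv + (n1 + 1) * j;
      for (int i = 0; i <= n1; ++i) {
        double v = col[i];
        if (v == 0.0) continue;
        const double* Pc = P1p + ld1 * i;
        double* tc = tmp.data() + n1 * j;
        for (int a = 0; a < n1; ++a) tc[a] += Pc[a] * v;
      }
    }
    psi.assign(n1 * (n2 + 2), 0.0);
    const double* J2p = J2.begin(); int ldj2 = J2.nrow();
    for (int j = 0; j <= n2; ++j) {
      const double* Jc = J2p + ldj2 * j;
      const double* tc = tmp.data() + n1 * j;
      for (int b = 0; b <= n2 + 1; ++b) {
        double w = Jc[b];
        if (w == 0.0) continue;
        double* pc = psi.data() + n1 * b;
        for (int a = 0; a < n1; ++a) pc[a] += tc[a] * w;
      }
    }
    auto PSI = [&](int a, int b) -> double {
      if (a < 0 || a >= n1 || b < 0 || b > n2 + 1) return 0.0;
      return psi[a + n1 * b];
    };
    for (int j = 0; j <= n2; ++j)
      for (int i = 0; i <= n1; ++i) {
        double t = n1 * ((double)(j + 1) / (n2 + 1)) * (PSI(i - 1, j + 1) - PSI(i, j + 1))
                   - (double)i * phi.get(i, j) + (double)(i + 1) * phi.get(i + 1, j);
        out[i + (n1 + 1) * j] += Min1 * t;
      }
  }
  if (Min2 > 0.0) {
    // Psi2(a, b): a = 0..n1+1 (jackknifed axis 1), b = 0..n2-1 (downsampled axis 2)
    static thread_local std::vector<double> tmp, psi;
    tmp.assign((n1 + 2) * (n2 + 1), 0.0); // J1 %*% phi
    const double* J1p = J1.begin(); int ldj1 = J1.nrow();
    for (int j = 0; j <= n2; ++j) {
      const double* col = pv + (n1 + 1) * j;
      double* tc = tmp.data() + (n1 + 2) * j;
      for (int i = 0; i <= n1; ++i) {
        double v = col[i];
        if (v == 0.0) continue;
        const double* Jc = J1p + ldj1 * i;
        for (int a = 0; a <= n1 + 1; ++a) tc[a] += Jc[a] * v;
      }
    }
    psi.assign((n1 + 2) * n2, 0.0);
    const double* P2p = P2.begin(); int ldp2 = P2.nrow();
    for (int j = 0; j <= n2; ++j) {
      const double* Pc = P2p + ldp2 * j;
      const double* tc = tmp.data() + (n1 + 2) * j;
      for (int b = 0; b < n2; ++b) {
        double w = Pc[b];
        if (w == 0.0) continue;
        double* pc = psi.data() + (n1 + 2) * b;
        for (int a = 0; a <= n1 + 1; ++a) pc[a] += tc[a] * w;
      }
    }
    auto PSI = [&](int a, int b) -> double {
      if (a < 0 || a > n1 + 1 || b < 0 || b >= n2) return 0.0;
      return psi[a + (n1 + 2) * b];
    };
    for (int j = 0; j <= n2; ++j)
      for (int i = 0; i <= n1; ++i) {
        double t = n2 * ((double)(i + 1) / (n1 + 1)) * (PSI(i + 1, j - 1) - PSI(i + 1, j))
                   - (double)j * phi.get(i, j) + (double)(j + 1) * phi.get(i, j + 1);
        out[i + (n1 + 1) * j] += Min2 * t;
      }
  }
}

// [[Rcpp::export(name = ".sfs_2d_engine_cpp")]]
NumericMatrix sfs_2d_engine_cpp(int n1, int n2, NumericMatrix ep, double theta,
                                double dt_fac, int max_steps,
                                NumericMatrix J1, NumericMatrix J2,
                                NumericMatrix P1, NumericMatrix P2) {
  int ntot = n1 + n2;
  // 1D ancestral phase at pooled size
  std::vector<double> phi1(ntot + 1, 0.0);
  for (int i = 1; i < ntot; ++i) phi1[i] = theta / i;
  double b1 = ntot * theta / 2.0;
  int r = 0, ne = ep.nrow();
  for (; r < ne && (int)ep(r, 1) == 1; ++r) {
    double T = ep(r, 0), nus = ep(r, 2), nue = ep(r, 3);
    int dyn = (int)ep(r, 4);
    double numin = (dyn == 0) ? nue : std::min(nus, nue);
    double dt = std::min(T / 50.0, dt_fac * 4.0 * numin / ((double)ntot * ntot));
    int steps = std::min(max_steps, std::max(1, (int)std::ceil(T / dt)));
    double h = T / steps;
    for (int s = 0; s < steps; ++s)
      cn_drift_1d(phi1, ntot, h, nu_fwd((s + 0.5) / steps, nus, nue, dyn), b1);
  }
  // split: hypergeometric redistribution of pooled counts over the two samples
  Grid phi; phi.n1 = n1; phi.n2 = n2; phi.v.assign((n1 + 1) * (n2 + 1), 0.0);
  {
    std::vector<double> lc(ntot + 1); // log choose(ntot, k) via lgamma
    auto lchoose_ = [](int n, int k) { return R::lchoose((double)n, (double)k); };
    for (int i = 0; i <= n1; ++i)
      for (int j = 0; j <= n2; ++j) {
        int k = i + j;
        double w = std::exp(lchoose_(n1, i) + lchoose_(n2, j) - lchoose_(ntot, k));
        phi.at(i, j) = phi1[k] * w;
      }
    (void)lc;
  }
  std::vector<double> col1(n1 + 1), col2(n2 + 1);
  double bs1 = n1 * theta / 2.0, bs2 = n2 * theta / 2.0;
  int nmax = std::max(n1, n2);
  int nc = (n1 + 1) * (n2 + 1);
  std::vector<double> Lmat(nc * nc), Aimp(nc * nc), Bexp(nc * nc);
  std::vector<double> unit(nc), lcol(nc), rhs(nc);
  std::vector<int> ipiv(nc);
  for (; r < ne; ++r) {
    double T = ep(r, 0);
    double nu1s = ep(r, 2), nu1e = ep(r, 3); int dyn1 = (int)ep(r, 4);
    double nu2s = ep(r, 5), nu2e = ep(r, 6); int dyn2 = (int)ep(r, 7);
    double m12 = ep(r, 8), m21 = ep(r, 9);
    double numin = std::min((dyn1 == 0) ? nu1e : std::min(nu1s, nu1e),
                            (dyn2 == 0) ? nu2e : std::min(nu2s, nu2e));
    double dt = std::min(T / 50.0, dt_fac * 4.0 * numin / ((double)nmax * nmax));
    int steps = std::min(max_steps, std::max(1, (int)std::ceil(T / dt)));
    bool mig = (m12 > 0.0 || m21 > 0.0);
    // hybrid migration stepper: explicit RK2 when the stability-limited step
    // count stays modest (mild migration: the common case), A-stable dense
    // Crank-Nicolson (one LAPACK factorization per epoch) when stiff
    bool mig_explicit = false;
    if (mig) {
      double dt_ex = dt_fac / (2.0 * (m12 + m21) * nmax);
      int steps_ex = (int)std::ceil(T / std::min(dt, dt_ex));
      if (steps_ex <= std::max(3 * steps, 150) && steps_ex <= max_steps) {
        mig_explicit = true;
        steps = std::max(steps, steps_ex);
      }
    }
    double h = T / steps;
    if (mig && !mig_explicit) {
      // migration operator is constant in time: assemble it densely once per
      // epoch and advance with Crank-Nicolson (A-stable; no step-size limit
      // from migration stiffness). A = I - h/2 L factorized by LAPACK.
      Grid e; e.n1 = n1; e.n2 = n2;
      for (int c = 0; c < nc; ++c) {
        std::fill(unit.begin(), unit.end(), 0.0);
        unit[c] = 1.0;
        e.v = unit;
        mig_terms(e, P1, J2, P2, J1, m21, m12, lcol);
        for (int rr = 0; rr < nc; ++rr) Lmat[rr + nc * c] = lcol[rr];
      }
      for (int c = 0; c < nc; ++c)
        for (int rr = 0; rr < nc; ++rr) {
          double d = (rr == c) ? 1.0 : 0.0;
          Aimp[rr + nc * c] = d - 0.5 * h * Lmat[rr + nc * c];
          Bexp[rr + nc * c] = d + 0.5 * h * Lmat[rr + nc * c];
        }
      int info = 0;
      F77_CALL(dgetrf)(&nc, &nc, Aimp.data(), &nc, ipiv.data(), &info);
      if (info != 0) stop("LU factorization failed in migration step");
      // fold the solve into one matrix: Bexp <- Aimp^{-1} Bexp
      F77_CALL(dgetrs)("N", &nc, &nc, Aimp.data(), &nc, ipiv.data(),
                       Bexp.data(), &nc, &info FCONE);
      if (info != 0) stop("LU solve failed in migration step");
    }
    for (int s = 0; s < steps; ++s) {
      double f = (s + 0.5) / steps;
      double nu1 = nu_fwd(f, nu1s, nu1e, dyn1);
      double nu2 = nu_fwd(f, nu2s, nu2e, dyn2);
      // Strang splitting: drift1(h/2), drift2(h/2), migration(h), drift2, drift1
      static thread_local AxisCN ax1, ax2;
      ax1.setup(n1, h / 2.0, nu1);
      ax2.setup(n2, h / 2.0, nu2);
      for (int j = 0; j <= n2; ++j)
        ax1.lane(phi.v.data() + (n1 + 1) * j, 1, h / 2.0, (j == 0) ? bs1 : 0.0);
      for (int i = 0; i <= n1; ++i)
        ax2.lane(phi.v.data() + i, n1 + 1, h / 2.0, (i == 0) ? bs2 : 0.0);
      if (mig && mig_explicit) {
        // midpoint RK2 on the migration operator
        static thread_local std::vector<double> k1v, k2v;
        k1v.resize(phi.v.size()); k2v.resize(phi.v.size());
        mig_terms(phi, P1, J2, P2, J1, m21, m12, k1v);
        static thread_local Grid half;
        half.n1 = phi.n1; half.n2 = phi.n2; half.v = phi.v;
        for (size_t c = 0; c < phi.v.size(); ++c) half.v[c] += 0.5 * h * k1v[c];
        mig_terms(half, P1, J2, P2, J1, m21, m12, k2v);
        for (size_t c = 0; c < phi.v.size(); ++c) phi.v[c] += h * k2v[c];
      } else if (mig) {
        const double one = 1.0, zero = 0.0;
        const int ione = 1;
        F77_CALL(dgemv)("N", &nc, &nc, &one, Bexp.data(), &nc,
                        phi.v.data(), &ione, &zero, rhs.data(), &ione FCONE);
        std::copy(rhs.begin(), rhs.end(), phi.v.begin());
      }
      for (int i = 0; i <= n1; ++i)
        ax2.lane(phi.v.data() + i, n1 + 1, h / 2.0, (i == 0) ? bs2 : 0.0);
      for (int j = 0; j <= n2; ++j)
        ax1.lane(phi.v.data() + (n1 + 1) * j, 1, h / 2.0, (j == 0) ? bs1 : 0.0);
    }
    for (double x : phi.v)
      if (!R_FINITE(x))
        stop("non-finite spectrum during epoch %d; parameters too extreme", r + 1);
  }
  NumericMatrix out(n1 + 1, n2 + 1);
  for (int j = 0; j <= n2; ++j)
    for (int i = 0; i <= n1; ++i) out(i, j) = std::max(0.0, phi.get(i, j));
  return out;
}
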