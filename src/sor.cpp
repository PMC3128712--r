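// Successive over-relaxation kernel for the finite-difference linearized
// Poisson-Boltzmann equation. Node update (uniform spacing h, kT/e units):
//   phi_i = (sum_f eps_f phi_nbr + 4 pi C q_i / h) / (sum_f eps_f + kap2h2_i)
// with eps_f the harmonic mean of the two adjacent node dielectrics and
// kap2h2 = eps_s kappa^2 h^2 on ion-accessible nodes, 0 elsewhere.
// Boundary nodes are Dirichlet (never updated).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double hmean(double a, double b) {
  return 2.0 * a * b / (a + b);
}

// [[Rcpp::export]]
List sor_lpb(NumericVector eps, NumericVector kap2h2, NumericVector src,
             NumericVector phi0, IntegerVector dims, double omega,
             double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(phi0);
  double *p = REAL(phi);
  const double *e = REAL(eps);
  const double *k2 = REAL(kap2h2);
  const double *s = REAL(src);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  std::vector<double> hist;
  hist.reserve(256);
  double maxdiff = R_PosInf;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    maxdiff = 0.0;
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        R_xlen_t id = sx + sy * j + sz * k;
        for (int i = 1; i < nx - 1; ++i, ++id) {
          const double e0 = e[id];
          const double exm = hmean(e0, e[id - sx]), exp_ = hmean(e0, e[id + sx]);
          const double eym = hmean(e0, e[id - sy]), eyp = hmean(e0, e[id + sy]);
          const double ezm = hmean(e0, e[id - sz]), ezp = hmean(e0, e[id + sz]);
          const double num = exm * p[id - sx] + exp_ * p[id + sx]
                           + eym * p[id - sy] + eyp * p[id + sy]
                           + ezm * p[id - sz] + ezp * p[id + sz] + s[id];
          const double den = exm + exp_ + eym + eyp + ezm + ezp + k2[id];
          const double d = omega * (num / den - p[id]);
          p[id] += d;
          const double ad = std::fabs(d);
          if (ad > maxdiff) maxdiff = ad;
        }
      }
    }
    hist.push_back(maxdiff);
    if (maxdiff < tol) break;
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  const bool converged = maxdiff < tol;
  if (it > maxit) it = maxit;

  // residual of the discrete operator at the final iterate
  double maxres = 0.0;
  for (int k = 1; k < nz - 1; ++k) {
    for (int j = 1; j < ny - 1; ++j) {
      R_xlen_t id = sx + sy * j + sz * k;
      for (int i = 1; i < nx - 1; ++i, ++id) {
        const double e0 = e[id];
        const double exm = hmean(e0, e[id - sx]), exp_ = hmean(e0, e[id + sx]);
        const double eym = hmean(e0, e[id - sy]), eyp = hmean(e0, e[id + sy]);
        const double ezm = hmean(e0, e[id - sz]), ezp = hmean(e0, e[id + sz]);
        const double num = exm * p[id - sx] + exp_ * p[id + sx]
                         + eym * p[id - sy] + eyp * p[id + sy]
                         + ezm * p[id - sz] + ezp * p[id + sz] + s[id];
        const double den = exm + exp_ + eym + eyp + ezm + ezp + k2[id];
        const double r = std::fabs(num - den * p[id]);
        if (r > maxres) maxres = r;
      }
    }
  }

  return List::create(_["phi"] = phi,
                      _["iterations"] = it,
                      _["converged"] = converged,
                      _["max_update"] = maxdiff,
                      _["max_residual"] = maxres,
                      _["history"] = wrap(hist));
}
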