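// Batched evaluation of the grid log-likelihood
//
//   log L(theta, t | M, N) = sum_k log f(m_k | theta, t, n_k)
//   f(m | theta, t, n)    = int_0^1 Binom(m | n, x) psi(x | theta, t) dx
//
// where psi is the density of x = (1 - theta) v + theta u with
// v ~ Beta(a0, b0), u ~ Beta(at, bt).  The integral is computed by an
// exact-cell-mass discretization: the distributions of (1 - theta) v and
// theta u are reduced to probability masses over uniform cells of width
// h = 1/G (masses from the regularized incomplete beta function, so
// endpoint-singular betas are handled exactly), the mass vector of x is
// their discrete convolution, and f is the mass-weighted sum of the
// binomial pmf over the cell centers.  The per-cluster quantities for all
// (theta, t) grid points and all samples reduce to one small matrix
// product per cluster.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Probability masses of L * Beta(a, b) over cells centered at i*h,
// i = 0..G (cell i covers [max(0,(i-.5)h), (i+.5)h]).  Returns the number
// of cells that can be non-zero.
static int comp_mass(double L, double a, double b, double h, int G,
                     arma::vec &out) {
  out.zeros();
  if (L <= 0.0) { out[0] = 1.0; return 1; }
  double prev = 0.0;
  int i = 0;
  for (; i <= G; ++i) {
    double up = (i + 0.5) * h;
    double q = (up >= L) ? 1.0 : R::pbeta(up / L, a, b, 1, 0);
    out[i] = q - prev;
    prev = q;
    if (up >= L) { ++i; break; }
  }
  return i;
}

// [[Rcpp::export(name = ".loglik_grid_cpp")]]
List loglik_grid_cpp(IntegerMatrix M, IntegerMatrix N,
                     NumericVector a0, NumericVector b0,
                     NumericMatrix aT, NumericMatrix bT,
                     int J, int G) {
  const int S = M.nrow(), K = M.ncol(), T = aT.ncol();
  if (N.nrow() != S || N.ncol() != K || aT.nrow() != K)
    stop("inconsistent input dimensions");
  if (J < 2 || G < 8) stop("J must be >= 2 and G >= 8");
  const double h = 1.0 / G;
  const int nx = G + 1;              // x support grid: r*h, r = 0..G
  const int R_rows = 1 + T * (J - 1);

  // binomial pmf needs log(x), log(1-x); pull endpoints off 0 and 1
  arma::vec lx(nx), l1x(nx);
  for (int r = 0; r < nx; ++r) {
    double x = std::min(std::max(r * h, h / 4.0), 1.0 - h / 4.0);
    lx[r] = std::log(x);
    l1x[r] = std::log1p(-x);
  }

  arma::mat LL(R_rows, S, arma::fill::zeros);
  arma::vec A(G + 1), B(G + 1);
  arma::mat Psi(R_rows, nx);
  arma::mat D(nx, S);
  IntegerVector Kused(S);

  for (int k = 0; k < K; ++k) {
    Psi.zeros();
    // theta = 0: x = v exactly
    comp_mass(1.0, a0[k], b0[k], h, G, A);
    Psi.row(0) = A.t();
    for (int j = 1; j < J; ++j) {
      const double theta = (double)j / J;
      const int nA = comp_mass(1.0 - theta, a0[k], b0[k], h, G, A);
      for (int t = 0; t < T; ++t) {
        const int nB = comp_mass(theta, aT(k, t), bT(k, t), h, G, B);
        arma::rowvec acc(nx, arma::fill::zeros);
        for (int jj = 0; jj < nB; ++jj) {
          const double bj = B[jj];
          if (bj <= 0.0) continue;
          const int top = std::min(nA, nx - jj);
          double *p = acc.memptr() + jj;
          const double *ap = A.memptr();
          for (int i = 0; i < top; ++i) p[i] += ap[i] * bj;
          // boundary half-cells can spill past x = 1; fold the mass back so
          // every psi row keeps total mass exactly 1
          for (int i = top; i < nA; ++i) acc[nx - 1] += ap[i] * bj;
        }
        Psi.row(1 + t * (J - 1) + (j - 1)) = acc;
      }
    }

    // binomial pmf of every sample at the cell centers
    for (int s = 0; s < S; ++s) {
      const int n = N(s, k), m = M(s, k);
      if (n <= 0) {                  // unusable cluster: contributes log 1
        D.col(s).ones();
        continue;
      }
      Kused[s] += 1;
      const double lf = R::lgammafn(n + 1.0) - R::lgammafn(m + 1.0) -
                        R::lgammafn(n - m + 1.0);
      double *d = D.colptr(s);
      for (int r = 0; r < nx; ++r) {
        const double lp = lf + m * lx[r] + (n - m) * l1x[r];
        d[r] = (lp < -745.0) ? 0.0 : std::exp(lp);
      }
    }

    arma::mat F = Psi * D;           // R_rows x S cluster likelihoods
    F.transform([](double v) { return v < 1e-300 ? 1e-300 : v; });
    LL += arma::log(F);
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["loglik"] = LL, _["K_used"] = Kused);
}
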