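// Conjugate gradients with an ILU(0) preconditioner on the linear-basis
// block. The system matrix is symmetric and passed in compressed sparse
// column form, which for a symmetric matrix is also its CSR form; all
// routines below read it as CSR with sorted column indices.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List ilu0_factor_csr(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                     int n) {
  NumericVector lu = clone(Ax);
  IntegerVector diagp(n, -1);
  std::vector<int> w((size_t) n, -1);
  for (int i = 0; i < n; ++i) {
    int rs = Ap[i], re = Ap[i + 1];
    for (int p = rs; p < re; ++p) {
      w[Ai[p]] = p;
      if (Ai[p] == i) diagp[i] = p;
    }
    for (int p = rs; p < re; ++p) {
      int k = Ai[p];
      if (k >= i) break;
      double piv = lu[diagp[k]];
      if (piv == 0.0) stop("zero pivot in ILU(0) at row %d", k + 1);
      double mult = lu[p] / piv;
      lu[p] = mult;
      for (int q = diagp[k] + 1; q < Ap[k + 1]; ++q) {
        int pos = w[Ai[q]];
        if (pos >= 0) lu[pos] -= mult * lu[q];
      }
    }
    if (diagp[i] < 0 || lu[diagp[i]] == 0.0)
      stop("zero pivot in ILU(0) at row %d", i + 1);
    for (int p = rs; p < re; ++p) w[Ai[p]] = -1;
  }
  return List::create(_["lu"] = lu, _["diag"] = diagp);
}

static void ilu0_apply(const int *Ap, const int *Ai, const double *lu,
                       const int *diagp, int n, const double *b, double *x) {
  for (int i = 0; i < n; ++i) {
    double s = b[i];
    for (int p = Ap[i]; p < diagp[i]; ++p) s -= lu[p] * x[Ai[p]];
    x[i] = s;
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = x[i];
    for (int p = diagp[i] + 1; p < Ap[i + 1]; ++p) s -= lu[p] * x[Ai[p]];
    x[i] = s / lu[diagp[i]];
  }
}

// [[Rcpp::export]]
NumericVector ilu0_solve_csr(IntegerVector Ap, IntegerVector Ai,
                             NumericVector lu, IntegerVector diagp,
                             NumericVector b) {
  int n = diagp.size();
  NumericVector x(n);
  ilu0_apply(Ap.begin(), Ai.begin(), lu.begin(), diagp.begin(), n,
             b.begin(), x.begin());
  return x;
}

static void sym_matvec(const int *Ap, const int *Ai, const double *Ax, int n,
                       const double *x, double *y) {
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int p = Ap[i]; p < Ap[i + 1]; ++p) s += Ax[p] * x[Ai[p]];
    y[i] = s;
  }
}

// Preconditioned CG: ILU(0) of the leading nb x nb (linear) block,
// Jacobi (diagonal) on the remaining higher-order modes.
// [[Rcpp::export]]
List pcg_ilu_csr(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                 NumericVector b, NumericVector x0, double tol, int maxit,
                 int nb, IntegerVector Lp, IntegerVector Li, NumericVector Lx,
                 IntegerVector Ldiag, NumericVector diag_rest) {
  int n = b.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> r((size_t) n), z((size_t) n), pv((size_t) n),
      apv((size_t) n);
  sym_matvec(Ap.begin(), Ai.begin(), Ax.begin(), n, x.data(), r.data());
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = b[i] - r[i];
    bnorm += b[i] * b[i];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;
  double rnorm = 0.0;
  for (int i = 0; i < n; ++i) rnorm += r[i] * r[i];
  rnorm = std::sqrt(rnorm);
  int it = 0;
  auto precond = [&](const std::vector<double> &rr, std::vector<double> &zz) {
    ilu0_apply(Lp.begin(), Li.begin(), Lx.begin(), Ldiag.begin(), nb,
               rr.data(), zz.data());
    for (int i = nb; i < n; ++i) zz[i] = rr[i] / diag_rest[i - nb];
  };
  if (rnorm > tol * bnorm) {
    precond(r, z);
    pv = z;
    double rz = 0.0;
    for (int i = 0; i < n; ++i) rz += r[i] * z[i];
    for (it = 1; it <= maxit; ++it) {
      sym_matvec(Ap.begin(), Ai.begin(), Ax.begin(), n, pv.data(), apv.data());
      double pap = 0.0;
      for (int i = 0; i < n; ++i) pap += pv[i] * apv[i];
      if (pap <= 0.0) stop("PCG breakdown (non-positive curvature) at iteration %d", it);
      double alpha = rz / pap;
      rnorm = 0.0;
      for (int i = 0; i < n; ++i) {
        x[i] += alpha * pv[i];
        r[i] -= alpha * apv[i];
        rnorm += r[i] * r[i];
      }
      rnorm = std::sqrt(rnorm);
      if (rnorm <= tol * bnorm) break;
      precond(r, z);
      double rz_new = 0.0;
      for (int i = 0; i < n; ++i) rz_new += r[i] * z[i];
      double beta = rz_new / rz;
      rz = rz_new;
      for (int i = 0; i < n; ++i) pv[i] = z[i] + beta * pv[i];
    }
    if (rnorm > tol * bnorm)
      stop("PCG did not converge in %d iterations (relres %g)", maxit,
           rnorm / bnorm);
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = it,
                      _["relres"] = rnorm / bnorm);
}
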