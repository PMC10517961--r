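// Preconditioned conjugate gradients for the grounded admittance system.
//
// The nodal matrix arrives as a symmetric dgCMatrix (full pattern, CSC).
// One node (`ref`, 0-based) is grounded before solving: its row and column
// are dropped and replaced by an identity equation, which turns the
// singular network Laplacian into an SPD system. The preconditioner is a
// shifted incomplete Cholesky IC(0); if the factorization breaks down even
// after diagonal shifting we fall back to Jacobi.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct CSC {
  std::vector<int> p, i;
  std::vector<double> x;
  int n;
};

// Drop row/col `ref`, put 1 on its diagonal.
CSC ground(const IntegerVector& Ap, const IntegerVector& Ai,
           const NumericVector& Ax, int n, int ref) {
  CSC A;
  A.n = n;
  A.p.assign(n + 1, 0);
  A.i.reserve(Ai.size());
  A.x.reserve(Ax.size());
  for (int j = 0; j < n; ++j) {
    A.p[j] = (int)A.i.size();
    if (j == ref) {
      A.i.push_back(ref);
      A.x.push_back(1.0);
      continue;
    }
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) {
      int r = Ai[k];
      if (r == ref) continue;
      A.i.push_back(r);
      A.x.push_back(Ax[k]);
    }
  }
  A.p[n] = (int)A.i.size();
  return A;
}

void matvec(const CSC& A, const double* v, double* out) {
  std::fill(out, out + A.n, 0.0);
  for (int j = 0; j < A.n; ++j) {
    double vj = v[j];
    for (int k = A.p[j]; k < A.p[j + 1]; ++k)
      out[A.i[k]] += A.x[k] * vj;
  }
}

// Lower-triangular part of A in CSC (column-major, diagonal first).
CSC lower(const CSC& A) {
  CSC L;
  L.n = A.n;
  L.p.assign(A.n + 1, 0);
  for (int j = 0; j < A.n; ++j) {
    L.p[j] = (int)L.i.size();
    // diagonal first
    for (int k = A.p[j]; k < A.p[j + 1]; ++k)
      if (A.i[k] == j) { L.i.push_back(j); L.x.push_back(A.x[k]); }
    for (int k = A.p[j]; k < A.p[j + 1]; ++k)
      if (A.i[k] > j) { L.i.push_back(A.i[k]); L.x.push_back(A.x[k]); }
  }
  L.p[A.n] = (int)L.i.size();
  return L;
}

// IC(0) on the lower-triangular pattern; returns false on breakdown.
bool ic0(CSC& L, double shift) {
  int n = L.n;
  if (shift > 0.0)
    for (int j = 0; j < n; ++j) L.x[L.p[j]] *= (1.0 + shift);
  std::vector<int> head(n, -1), next(L.i.size(), -1), pos(n, 0);
  for (int j = 0; j < n; ++j) {
    int kd = L.p[j];
    double dj = L.x[kd];
    if (dj <= 0.0) return false;
    dj = std::sqrt(dj);
    L.x[kd] = dj;
    for (int k = kd + 1; k < L.p[j + 1]; ++k) L.x[k] /= dj;
    // scatter column j into later columns: for each pair (r1, r2) with
    // r1 <= r2 in column j, A(r2, r1) -= L(r1,j) * L(r2,j) when r1 is a
    // future column.
    for (int k1 = kd + 1; k1 < L.p[j + 1]; ++k1) {
      int c = L.i[k1];              // future column to update
      double ljc = L.x[k1];
      // walk column c and subtract matching entries
      int k2 = k1;
      int kc = L.p[c];
      int kcend = L.p[c + 1];
      for (; k2 < L.p[j + 1]; ++k2) {
        int r = L.i[k2];
        while (kc < kcend && L.i[kc] < r) ++kc;
        if (kc < kcend && L.i[kc] == r)
          L.x[kc] -= ljc * L.x[k2];
      }
    }
  }
  return true;
}

// Solve L L^T z = r
void ic_solve(const CSC& L, const double* r, double* z, double* tmp) {
  int n = L.n;
  // forward: L y = r  (L is CSC lower with diag first per column)
  for (int j = 0; j < n; ++j) tmp[j] = r[j];
  for (int j = 0; j < n; ++j) {
    double yj = tmp[j] / L.x[L.p[j]];
    tmp[j] = yj;
    for (int k = L.p[j] + 1; k < L.p[j + 1]; ++k)
      tmp[L.i[k]] -= L.x[k] * yj;
  }
  // backward: L^T z = y
  for (int j = 0; j < n; ++j) z[j] = tmp[j];
  for (int j = n - 1; j >= 0; --j) {
    double s = z[j];
    for (int k = L.p[j] + 1; k < L.p[j + 1]; ++k)
      s -= L.x[k] * z[L.i[k]];
    z[j] = s / L.x[L.p[j]];
  }
}

} // namespace

// [[Rcpp::export(name = ".pcg_solve")]]
List pcg_solve(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
               NumericVector b, int ref, double tol, int maxit,
               std::string precond = "ic0") {
  int n = b.size();
  CSC A = ground(Ap, Ai, Ax, n, ref);
  NumericVector bb = clone(b);
  bb[ref] = 0.0;

  bool use_ic = (precond == "ic0");
  CSC L;
  if (use_ic) {
    L = lower(A);
    CSC Lsave = L;
    double shift = 0.0;
    bool ok = ic0(L, shift);
    int tries = 0;
    while (!ok && tries < 6) {
      shift = (shift == 0.0) ? 1e-3 : shift * 10.0;
      L = Lsave;
      ok = ic0(L, shift);
      ++tries;
    }
    if (!ok) use_ic = false;
  }
  std::vector<double> dinv(n);
  if (!use_ic) {
    for (int j = 0; j < n; ++j)
      for (int k = A.p[j]; k < A.p[j + 1]; ++k)
        if (A.i[k] == j) dinv[j] = 1.0 / A.x[k];
  }

  std::vector<double> x(n, 0.0), r(n), z(n), p(n), Apv(n), tmp(n);
  double bnorm = 0.0;
  for (int j = 0; j < n; ++j) { r[j] = bb[j]; bnorm += bb[j] * bb[j]; }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0)
    return List::create(_["x"] = NumericVector(n), _["iterations"] = 0,
                        _["relres"] = 0.0, _["precond"] = precond);

  auto apply_prec = [&](const double* rr, double* zz) {
    if (use_ic) ic_solve(L, rr, zz, tmp.data());
    else for (int j = 0; j < n; ++j) zz[j] = dinv[j] * rr[j];
  };

  apply_prec(r.data(), z.data());
  std::copy(z.begin(), z.end(), p.begin());
  double rz = 0.0;
  for (int j = 0; j < n; ++j) rz += r[j] * z[j];

  double relres = 1.0;
  int it = 0;
  for (; it < maxit; ++it) {
    matvec(A, p.data(), Apv.data());
    double pAp = 0.0;
    for (int j = 0; j < n; ++j) pAp += p[j] * Apv[j];
    if (pAp <= 0.0) break;
    double alpha = rz / pAp;
    double rn = 0.0;
    for (int j = 0; j < n; ++j) {
      x[j] += alpha * p[j];
      r[j] -= alpha * Apv[j];
      rn += r[j] * r[j];
    }
    relres = std::sqrt(rn) / bnorm;
    if (relres <= tol) { ++it; break; }
    apply_prec(r.data(), z.data());
    double rz_new = 0.0;
    for (int j = 0; j < n; ++j) rz_new += r[j] * z[j];
    double beta = rz_new / rz;
    rz = rz_new;
    for (int j = 0; j < n; ++j) p[j] = z[j] + beta * p[j];
  }

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = it,
                      _["relres"] = relres,
                      _["precond"] = use_ic ? "ic0" : "jacobi");
}
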