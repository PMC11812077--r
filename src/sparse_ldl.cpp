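// Sparse LDL' factorization (up-looking, elimination-tree based), triangular
// solves, and the Takahashi inverse-subset recurrence used by EM-REML trace
// computations. The factorization tolerates rank-deficient systems: pivots
// numerically zero relative to the original diagonal are set to zero, which
// yields the generalized inverse with the corresponding equations constrained
// to zero (the usual operational-zero treatment in animal-breeding solvers).
//
// Input matrices are the UPPER triangle (including diagonal) in
// column-compressed form with sorted row indices, already permuted by a
// fill-reducing ordering on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".ldl_factor_cpp")]]
List ldl_factor_cpp(int n, IntegerVector Ap, IntegerVector Ai,
                    NumericVector Ax, double rel_tol) {
  std::vector<int> Parent(n, -1), Flag(n, -1), Lnz(n, 0), Pattern(n);
  // symbolic: elimination tree and column counts
  for (int k = 0; k < n; ++k) {
    Flag[k] = k;
    for (int p = Ap[k]; p < Ap[k + 1]; ++p) {
      int i = Ai[p];
      while (i < k && Flag[i] != k) {
        if (Parent[i] == -1) Parent[i] = k;
        Lnz[i]++;
        Flag[i] = k;
        i = Parent[i];
      }
    }
  }
  IntegerVector Lp(n + 1);
  Lp[0] = 0;
  for (int k = 0; k < n; ++k) Lp[k + 1] = Lp[k] + Lnz[k];
  int lnz_total = Lp[n];
  IntegerVector Li(lnz_total);
  NumericVector Lx(lnz_total), D(n);
  NumericVector diag_orig(n);
  for (int k = 0; k < n; ++k) {
    for (int p = Ap[k]; p < Ap[k + 1]; ++p)
      if (Ai[p] == k) diag_orig[k] = Ax[p];
  }
  std::vector<double> Y(n, 0.0);
  std::vector<int> Lnz_work(n, 0), Stack(n);
  std::fill(Flag.begin(), Flag.end(), -1);
  int n_zero = 0;
  for (int k = 0; k < n; ++k) {
    int top = n;
    Flag[k] = k;
    double d = 0.0;
    for (int p = Ap[k]; p < Ap[k + 1]; ++p) {
      int i = Ai[p];
      if (i > k) stop("matrix must be upper triangular");
      if (i == k) {
        d = Ax[p];
        continue;
      }
      Y[i] += Ax[p];
      int len = 0;
      while (Flag[i] != k) {
        Pattern[len++] = i;
        Flag[i] = k;
        i = Parent[i];
      }
      while (len > 0) Stack[--top] = Pattern[--len];
    }
    for (int s = top; s < n; ++s) {
      int i = Stack[s];
      double yi = Y[i];
      Y[i] = 0.0;
      int p2 = Lp[i] + Lnz_work[i];
      for (int p = Lp[i]; p < p2; ++p) Y[Li[p]] -= Lx[p] * yi;
      double l_ki = (D[i] != 0.0) ? yi / D[i] : 0.0;
      d -= l_ki * yi;
      Li[p2] = k;
      Lx[p2] = l_ki;
      Lnz_work[i]++;
    }
    // operational zero, judged per equation against its own diagonal
    double thr = rel_tol * std::fabs(diag_orig[k]);
    if (d <= thr) { // zero or indefinite pivot -> constrain equation k
      D[k] = 0.0;
      n_zero++;
    } else {
      D[k] = d;
    }
  }
  return List::create(_["Lp"] = Lp, _["Li"] = Li, _["Lx"] = Lx, _["D"] = D,
                      _["n_zero_pivots"] = n_zero);
}

// [[Rcpp::export(name = ".ldl_solve_cpp")]]
NumericMatrix ldl_solve_cpp(IntegerVector Lp, IntegerVector Li,
                            NumericVector Lx, NumericVector D,
                            NumericMatrix B) {
  int n = D.size(), m = B.ncol();
  NumericMatrix X(n, m);
  for (int c = 0; c < m; ++c) {
    std::vector<double> x(n);
    for (int i = 0; i < n; ++i) x[i] = B(i, c);
    for (int j = 0; j < n; ++j) { // L z = b
      double xj = x[j];
      if (xj != 0.0)
        for (int p = Lp[j]; p < Lp[j + 1]; ++p) x[Li[p]] -= Lx[p] * xj;
    }
    for (int j = 0; j < n; ++j) x[j] = (D[j] != 0.0) ? x[j] / D[j] : 0.0;
    for (int j = n - 1; j >= 0; --j) { // L' x = z
      double xj = x[j];
      for (int p = Lp[j]; p < Lp[j + 1]; ++p) xj -= Lx[p] * x[Li[p]];
      x[j] = xj;
    }
    for (int i = 0; i < n; ++i) X(i, c) = x[i];
  }
  return X;
}

static inline double z_entry(const int *Zp, const int *Zi, const double *Zx,
                             const double *Zd, int r, int c) {
  // symmetric lookup; stored lower triangle by column, sorted rows
  if (r == c) return Zd[r];
  int col = r < c ? r : c, row = r < c ? c : r;
  int lo = Zp[col], hi = Zp[col + 1] - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (Zi[mid] == row) return Zx[mid];
    if (Zi[mid] < row) lo = mid + 1; else hi = mid - 1;
  }
  return 0.0;
}

// [[Rcpp::export(name = ".takahashi_cpp")]]
List takahashi_cpp(IntegerVector Lp, IntegerVector Li, NumericVector Lx,
                   NumericVector D) {
  int n = D.size();
  NumericVector Zx(Lx.size()), Zd(n);
  const int *lp = Lp.begin(), *li = Li.begin();
  const double *lx = Lx.begin();
  double *zx = Zx.begin(), *zd = Zd.begin();
  // For column j we need out[b] = sum_a L(S[a],j) * Z(S[a],S[b]) over the
  // column pattern S (all > j). Every needed Z element lies inside the
  // already-computed trailing columns (fill-path closure), so we walk each
  // column c in S once and scatter through a stamp array instead of
  // searching per pair.
  std::vector<int> pos(n, -1);
  std::vector<double> out, lval;
  for (int j = n - 1; j >= 0; --j) {
    int p0 = lp[j], p1 = lp[j + 1], m = p1 - p0;
    if (m > (int) out.size()) {
      out.resize(m);
      lval.resize(m);
    }
    for (int t = 0; t < m; ++t) {
      pos[li[p0 + t]] = t;
      lval[t] = lx[p0 + t];
      out[t] = 0.0;
    }
    for (int t = 0; t < m; ++t) {
      int c = li[p0 + t];
      out[t] += lval[t] * zd[c]; // diagonal Z(c,c)
      for (int p = lp[c]; p < lp[c + 1]; ++p) {
        int r = li[p]; // r > c, element Z(r,c)
        int a = pos[r];
        if (a >= 0) {
          double z = zx[p];
          out[t] += lval[a] * z; // (a -> row role, b = t)
          out[a] += lval[t] * z; // symmetric role
        }
      }
    }
    for (int t = 0; t < m; ++t) zx[p0 + t] = -out[t];
    double zjj = (D[j] != 0.0) ? 1.0 / D[j] : 0.0;
    for (int t = 0; t < m; ++t) zjj -= lval[t] * zx[p0 + t];
    zd[j] = (D[j] != 0.0) ? zjj : 0.0;
    for (int t = 0; t < m; ++t) pos[li[p0 + t]] = -1;
  }
  return List::create(_["Zx"] = Zx, _["Zdiag"] = Zd);
}

// Weighted sum of m x m blocks of Z: sum_k w_k * Z[rows_i[k,], rows_j[k,]].
// Row index matrices are 0-based permuted equation indices, one block per row.
// [[Rcpp::export(name = ".z_block_sum_cpp")]]
NumericMatrix z_block_sum_cpp(IntegerVector Lp, IntegerVector Li,
                              NumericVector Zx, NumericVector Zd,
                              IntegerMatrix rows_i, IntegerMatrix rows_j,
                              NumericVector w) {
  int K = rows_i.nrow(), m = rows_i.ncol();
  NumericMatrix out(m, m);
  const int *lp = Lp.begin(), *li = Li.begin();
  const double *zx = Zx.begin(), *zd = Zd.begin();
  for (int k = 0; k < K; ++k) {
    double wk = w[k];
    if (wk == 0.0) continue;
    for (int a = 0; a < m; ++a) {
      int ra = rows_i(k, a);
      for (int b = 0; b < m; ++b) {
        out(a, b) += wk * z_entry(lp, li, zx, zd, ra, rows_j(k, b));
      }
    }
  }
  return out;
}

// Per-record quadratic forms M_r Z M_r' over the record's design rows.
// Rows are described flat: row_ptr (length n_rows+1) delimits each row's
// (eq, val) pairs in eq/val; row_rec and row_trait give the record index and
// trait slot (0-based) of each row. Returns a 4 x 4 x n_rec array filled at
// observed trait pairs.
// [[Rcpp::export(name = ".record_quad_forms_cpp")]]
NumericVector record_quad_forms_cpp(IntegerVector Lp, IntegerVector Li,
                                    NumericVector Zx, NumericVector Zd,
                                    IntegerVector row_ptr, IntegerVector eq,
                                    NumericVector val, IntegerVector row_rec,
                                    IntegerVector row_trait, int n_rec,
                                    int n_traits) {
  int n_rows = row_ptr.size() - 1;
  NumericVector out(n_traits * n_traits * n_rec);
  out.attr("dim") = IntegerVector::create(n_traits, n_traits, n_rec);
  const int *lp = Lp.begin(), *li = Li.begin();
  const double *zx = Zx.begin(), *zd = Zd.begin();
  int r0 = 0;
  while (r0 < n_rows) {
    int rec = row_rec[r0];
    int r1 = r0;
    while (r1 < n_rows && row_rec[r1] == rec) ++r1;
    for (int a = r0; a < r1; ++a) {
      for (int b = a; b < r1; ++b) {
        double s = 0.0;
        for (int pa = row_ptr[a]; pa < row_ptr[a + 1]; ++pa) {
          double va = val[pa];
          int ea = eq[pa];
          for (int pb = row_ptr[b]; pb < row_ptr[b + 1]; ++pb) {
            s += va * val[pb] * z_entry(lp, li, zx, zd, ea, eq[pb]);
          }
        }
        int ta = row_trait[a], tb = row_trait[b];
        out[ta + n_traits * tb + n_traits * n_traits * rec] = s;
        out[tb + n_traits * ta + n_traits * n_traits * rec] = s;
      }
    }
    r0 = r1;
  }
  return out;
}
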