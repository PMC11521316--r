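#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dense two-phase primal simplex.
//
// Solves  max/min c'x  s.t.  A x (<=,=,>=) b,  lb <= x <= ub.
// Intended for the small and medium LPs arising from guild-level community
// models (a few hundred rows/columns); everything is kept dense and the
// bounded variables are handled by shifting/splitting plus explicit range
// rows, which keeps the pivoting code short and auditable.
//
// status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.

static const double INF = std::numeric_limits<double>::infinity();

struct Lp {
  int m = 0;                 // rows
  int ncol = 0;              // total columns incl. artificials, excl. rhs
  int nart = 0;              // artificial columns (last nart columns)
  std::vector<double> T;     // m x (ncol + 1), row-major, rhs last
  std::vector<int> basis;    // length m
  double &at(int i, int j) { return T[(size_t)i * (ncol + 1) + j]; }
};

static void pivot(Lp &lp, std::vector<double> &d, int r, int s) {
  int w = lp.ncol + 1;
  double piv = lp.at(r, s);
  for (int j = 0; j < w; ++j) lp.at(r, j) /= piv;
  for (int i = 0; i < lp.m; ++i) {
    if (i == r) continue;
    double f = lp.at(i, s);
    if (f == 0.0) continue;
    for (int j = 0; j < w; ++j) lp.at(i, j) -= f * lp.at(r, j);
    lp.at(i, s) = 0.0;
  }
  double f = d[s];
  if (f != 0.0) {
    for (int j = 0; j < w; ++j) d[j] -= f * lp.at(r, j);
    d[s] = 0.0;
  }
  lp.basis[r] = s;
}

// recompute reduced-cost row d (length ncol+1; last cell = -z) from costs c
static void reduced_costs(Lp &lp, const std::vector<double> &c,
                          std::vector<double> &d) {
  int w = lp.ncol + 1;
  d.assign(w, 0.0);
  for (int j = 0; j < lp.ncol; ++j) d[j] = c[j];
  for (int i = 0; i < lp.m; ++i) {
    double cb = c[lp.basis[i]];
    if (cb == 0.0) continue;
    for (int j = 0; j < w; ++j) d[j] -= cb * lp.at(i, j);
  }
}

// ratio test on column s; pivots below min_piv are ineligible. Among
// near-tied rows the largest pivot element wins (smallest basis index
// under Bland's rule). Returns the row, or -1.
static int ratio_test(Lp &lp, int s, double min_piv, bool bland) {
  int r = -1;
  double ratio = INF, bestpiv = 0.0;
  for (int i = 0; i < lp.m; ++i) {
    double a = lp.at(i, s);
    if (a < min_piv) continue;
    double q = lp.at(i, lp.ncol) / a;
    double slack = 1e-9 * (1.0 + (r >= 0 ? std::fabs(ratio) : 0.0));
    if (r < 0 || q < ratio - slack) {
      ratio = q; r = i; bestpiv = a;
    } else if (q < ratio + slack) {
      bool better = bland ? (lp.basis[i] < lp.basis[r]) : (a > bestpiv);
      if (better) { r = i; bestpiv = a; if (q < ratio) ratio = q; }
    }
  }
  return r;
}

// minimize over allowed columns; returns status
static int simplex_iterate(Lp &lp, std::vector<double> &d, int ncol_allowed,
                           int max_iter, double tol) {
  const double piv_tol = 1e-7;
  int iter = 0, stall = 0;
  double best = INF;
  while (true) {
    if (++iter > max_iter) return 3;
    bool bland = stall > 2000;
    // entering column: most negative reduced cost (first eligible under
    // Bland) among columns that admit a numerically safe pivot; columns
    // with no safe pivot are kept as a last resort, and a column with no
    // positive entry at all certifies unboundedness
    int s = -1, s_soft = -1;
    double most = -tol, most_soft = -tol;
    for (int j = 0; j < ncol_allowed; ++j) {
      if (d[j] >= ((bland && s >= 0) ? -INF : most) || d[j] >= -tol)
        continue;
      bool safe = false, any = false;
      for (int i = 0; i < lp.m; ++i) {
        double a = lp.at(i, j);
        if (a > piv_tol) { safe = true; break; }
        if (a > tol) any = true;
      }
      if (safe) {
        if (d[j] < most) { s = j; most = d[j]; }
        if (bland) break;
      } else if (!any) {
        return 2;                   // improving ray, nothing blocks it
      } else if (d[j] < most_soft) {
        s_soft = j; most_soft = d[j];
      }
    }
    double min_piv = piv_tol;
    if (s < 0) { s = s_soft; min_piv = tol; }
    if (s < 0) return 0;            // optimal
    int r = ratio_test(lp, s, min_piv, bland);
    if (r < 0) return 2;
    pivot(lp, d, r, s);
    double z = -d[lp.ncol];
    if (z < best - 1e-12) { best = z; stall = 0; } else ++stall;
  }
}

// [[Rcpp::export(name = ".cpp_simplex")]]
List cpp_simplex(NumericMatrix A, NumericVector b, IntegerVector sense,
                 NumericVector obj, bool maximize, NumericVector lower,
                 NumericVector upper, int max_iter = 200000,
                 double tol = 1e-9, double feas_tol = 1e-8) {
  int m0 = A.nrow(), n0 = A.ncol();

  // --- variable conversion: x -> nonnegative y -------------------------
  // kind 0: x = shift + y            (finite lb)
  // kind 1: x = shift - y            (lb = -Inf, finite ub)
  // kind 2: x = y_plus - y_minus     (free)
  std::vector<int> kind(n0), ycol(n0);
  std::vector<double> shift(n0, 0.0), range(n0, INF);
  int ny = 0;
  for (int j = 0; j < n0; ++j) {
    double lo = lower[j], hi = upper[j];
    if (lo > hi) return List::create(_["status"] = 1, _["objective"] = NA_REAL,
                                     _["x"] = NumericVector(n0));
    if (std::isfinite(lo)) {
      kind[j] = 0; shift[j] = lo; ycol[j] = ny++;
      if (std::isfinite(hi)) range[j] = hi - lo;
    } else if (std::isfinite(hi)) {
      kind[j] = 1; shift[j] = hi; ycol[j] = ny++;
    } else {
      kind[j] = 2; ycol[j] = ny; ny += 2;
    }
  }
  int nrange = 0;
  for (int j = 0; j < n0; ++j) if (std::isfinite(range[j])) ++nrange;
  int m = m0 + nrange;

  // rows over y variables, still with senses
  std::vector<std::vector<double>> R(m, std::vector<double>(ny, 0.0));
  std::vector<double> rhs(m, 0.0);
  std::vector<int> sn(m, 0);
  for (int i = 0; i < m0; ++i) {
    double bb = b[i];
    for (int j = 0; j < n0; ++j) {
      double a = A(i, j);
      if (a == 0.0) continue;
      bb -= a * shift[j];
      if (kind[j] == 0) R[i][ycol[j]] += a;
      else if (kind[j] == 1) R[i][ycol[j]] -= a;
      else { R[i][ycol[j]] += a; R[i][ycol[j] + 1] -= a; }
    }
    rhs[i] = bb;
    sn[i] = sense[i];
  }
  {
    int i = m0;
    for (int j = 0; j < n0; ++j) {
      if (!std::isfinite(range[j])) continue;
      R[i][ycol[j]] = 1.0;
      rhs[i] = range[j];
      sn[i] = -1;                    // y <= range
      ++i;
    }
  }

  // --- standard form with slacks, b >= 0, artificial basis -------------
  int nslack = 0;
  for (int i = 0; i < m; ++i) if (sn[i] != 0) ++nslack;
  Lp lp;
  lp.m = m;
  lp.nart = m;
  lp.ncol = ny + nslack + m;
  lp.T.assign((size_t)m * (lp.ncol + 1), 0.0);
  lp.basis.resize(m);
  int sj = ny;
  for (int i = 0; i < m; ++i) {
    double sgn = rhs[i] < 0 ? -1.0 : 1.0;
    for (int j = 0; j < ny; ++j) lp.at(i, j) = sgn * R[i][j];
    if (sn[i] == -1) lp.at(i, sj++) = sgn * 1.0;
    else if (sn[i] == 1) lp.at(i, sj++) = sgn * -1.0;
    lp.at(i, ny + nslack + i) = 1.0;     // artificial
    lp.at(i, lp.ncol) = sgn * rhs[i];
    lp.basis[i] = ny + nslack + i;
  }

  // --- phase 1 ----------------------------------------------------------
  // a simplex pass with drift control: reduced costs are recomputed from
  // scratch on termination and iteration resumes while any remain negative
  auto run = [&](const std::vector<double> &c, std::vector<double> &d,
                 int allowed) {
    int st = 0;
    for (int round = 0; round < 20; ++round) {
      reduced_costs(lp, c, d);
      bool neg = false;
      for (int j = 0; j < allowed; ++j)
        if (d[j] < -10 * tol) { neg = true; break; }
      if (round > 0 && !neg) break;
      st = simplex_iterate(lp, d, allowed, max_iter, tol);
      if (st != 0) break;
    }
    return st;
  };

  std::vector<double> c1(lp.ncol, 0.0), d;
  for (int j = ny + nslack; j < lp.ncol; ++j) c1[j] = 1.0;
  int st = run(c1, d, lp.ncol);
  double z1 = -d[lp.ncol];
  if (st == 3)
    return List::create(_["status"] = 3, _["objective"] = NA_REAL,
                        _["x"] = NumericVector(n0), _["phase1"] = z1);
  if (z1 > feas_tol)
    return List::create(_["status"] = 1, _["objective"] = NA_REAL,
                        _["x"] = NumericVector(n0), _["phase1"] = z1,
                        _["phase1_st"] = st);

  // drive leftover artificials out of the basis; drop redundant rows
  int nstruct = ny + nslack;
  for (int i = 0; i < lp.m; ++i) {
    if (lp.basis[i] < nstruct) continue;
    int s = -1;
    double amax = 1e-9;
    for (int j = 0; j < nstruct; ++j) {
      double a = std::fabs(lp.at(i, j));
      if (a > amax) { s = j; amax = a; }
    }
    if (s >= 0) {
      pivot(lp, d, i, s);
    } else {
      // redundant row: blank it so it can never bind
      for (int j = 0; j <= lp.ncol; ++j) lp.at(i, j) = 0.0;
      lp.at(i, lp.basis[i]) = 1.0;
    }
  }

  // --- phase 2 ----------------------------------------------------------
  std::vector<double> c2(lp.ncol, 0.0);
  double cshift = 0.0;               // objective value of the x-shifts
  for (int j = 0; j < n0; ++j) {
    double cj = maximize ? -obj[j] : obj[j];
    cshift += cj * shift[j];
    if (cj == 0.0) continue;
    if (kind[j] == 0) c2[ycol[j]] += cj;
    else if (kind[j] == 1) c2[ycol[j]] -= cj;
    else { c2[ycol[j]] += cj; c2[ycol[j] + 1] -= cj; }
  }
  st = run(c2, d, nstruct);
  if (st == 2 || st == 3)
    return List::create(_["status"] = st, _["objective"] = NA_REAL,
                        _["x"] = NumericVector(n0));

  std::vector<double> y(ny, 0.0);
  for (int i = 0; i < lp.m; ++i)
    if (lp.basis[i] < ny) y[lp.basis[i]] = lp.at(i, lp.ncol);
  NumericVector x(n0);
  for (int j = 0; j < n0; ++j) {
    if (kind[j] == 0) x[j] = shift[j] + y[ycol[j]];
    else if (kind[j] == 1) x[j] = shift[j] - y[ycol[j]];
    else x[j] = y[ycol[j]] - y[ycol[j] + 1];
  }
  double zmin = -d[lp.ncol] + cshift;
  double objective = maximize ? -zmin : zmin;
  return List::create(_["status"] = 0, _["objective"] = objective,
                      _["x"] = x);
}
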