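// Bounded-variable two-phase primal simplex for small dense LPs:
//   max (or min)  c'x   s.t.  A x = b,  l <= x <= u
// Written for flux-balance problems of at most a few hundred reactions;
// full-tableau updates are O(m*n) per pivot, which is cheap at that scale.
// Variables must have at least one finite bound (FBA reactions always do;
// inequality slacks have l = 0).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Tableau {
  int m, n;                 // rows; structural + artificial columns
  std::vector<double> T;    // m x (n+1) row-major; column n = basic values
  std::vector<int> basis;   // column basic in row i
  std::vector<int> state;   // 0 = nonbasic at lower, 1 = at upper, 2 = basic
  std::vector<double> lb, ub, val;  // val meaningful for nonbasic columns

  inline double &at(int i, int j) { return T[(size_t)i * (n + 1) + j]; }
};

// Returns 0 optimal, 2 unbounded, 3 iteration limit.
static int run_simplex(Tableau &tb, const std::vector<double> &cost,
                       bool maximize, double eps, int max_iter) {
  const int m = tb.m, n = tb.n;
  const double sgn = maximize ? 1.0 : -1.0;
  std::vector<double> d(n), cb(m);
  int iter = 0;
  bool bland = false;  // anti-cycling fallback

  while (true) {
    if (++iter > max_iter) {
      if (!bland) { bland = true; iter = 0; continue; }
      return 3;
    }
    for (int i = 0; i < m; ++i) cb[i] = sgn * cost[tb.basis[i]];
    for (int j = 0; j < n; ++j) {
      if (tb.state[j] == 2) { d[j] = 0.0; continue; }
      double z = 0.0;
      for (int i = 0; i < m; ++i) z += cb[i] * tb.at(i, j);
      d[j] = sgn * cost[j] - z;
    }
    // entering: nonbasic at lower with d > eps (increase), or at upper with
    // d < -eps (decrease)
    int enter = -1, dir = 0;
    double best = eps;
    for (int j = 0; j < n; ++j) {
      if (tb.state[j] == 2) continue;
      double gain = (tb.state[j] == 0) ? d[j] : -d[j];
      if (gain > best) {
        enter = j;
        dir = (tb.state[j] == 0) ? 1 : -1;
        if (bland) break;
        best = gain;
      }
    }
    if (enter < 0) return 0;

    // ratio test: entering moves t*dir from its bound; basics move -dir*t*y
    double tmax = tb.ub[enter] - tb.lb[enter];  // bound-flip distance
    int leave = -1, leave_at = 0;
    for (int i = 0; i < m; ++i) {
      double step = dir * tb.at(i, enter);
      double xb = tb.at(i, n);
      int bj = tb.basis[i];
      if (step > eps) {
        if (!std::isfinite(tb.lb[bj])) continue;
        double t = (xb - tb.lb[bj]) / step;
        if (t < tmax) { tmax = t; leave = i; leave_at = 0; }
      } else if (step < -eps) {
        if (!std::isfinite(tb.ub[bj])) continue;
        double t = (tb.ub[bj] - xb) / (-step);
        if (t < tmax) { tmax = t; leave = i; leave_at = 1; }
      }
    }
    if (!std::isfinite(tmax)) return 2;
    if (tmax < 0) tmax = 0;

    if (leave < 0) {
      // bound flip, basis unchanged
      for (int i = 0; i < m; ++i)
        tb.at(i, n) -= dir * tmax * tb.at(i, enter);
      tb.state[enter] = 1 - tb.state[enter];
      tb.val[enter] = (tb.state[enter] == 0) ? tb.lb[enter] : tb.ub[enter];
      continue;
    }

    double enter_val = tb.val[enter] + dir * tmax;
    int out = tb.basis[leave];
    for (int i = 0; i < m; ++i)
      tb.at(i, n) -= dir * tmax * tb.at(i, enter);
    tb.state[out] = leave_at;
    tb.val[out] = (leave_at == 0) ? tb.lb[out] : tb.ub[out];
    tb.at(leave, n) = enter_val;

    double piv = tb.at(leave, enter);
    for (int j = 0; j < n; ++j) tb.at(leave, j) /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double f = tb.at(i, enter);
      if (f == 0.0) continue;
      for (int j = 0; j < n; ++j) tb.at(i, j) -= f * tb.at(leave, j);
    }
    tb.basis[leave] = enter;
    tb.state[enter] = 2;
  }
}

// [[Rcpp::export(name = ".simplex_lp")]]
List simplex_lp(NumericMatrix A, NumericVector b, NumericVector lb,
                NumericVector ub, NumericVector cc, bool maximize = true,
                double eps = 1e-9, int max_iter = 20000) {
  const int m = A.nrow(), nvar = A.ncol();
  if (b.size() != m || lb.size() != nvar || ub.size() != nvar || cc.size() != nvar)
    stop("simplex: dimension mismatch");
  for (int j = 0; j < nvar; ++j)
    if (lb[j] > ub[j]) stop("simplex: lb > ub for column %d", j + 1);

  const int n = nvar + m;
  Tableau tb;
  tb.m = m; tb.n = n;
  tb.T.assign((size_t)m * (n + 1), 0.0);
  tb.basis.resize(m);
  tb.state.assign(n, 0);
  tb.lb.resize(n); tb.ub.resize(n); tb.val.resize(n);

  for (int j = 0; j < nvar; ++j) {
    tb.lb[j] = lb[j]; tb.ub[j] = ub[j];
    if (std::isfinite(lb[j])) { tb.state[j] = 0; tb.val[j] = lb[j]; }
    else if (std::isfinite(ub[j])) { tb.state[j] = 1; tb.val[j] = ub[j]; }
    else stop("simplex: column %d has no finite bound", j + 1);
  }
  std::vector<double> resid(m);
  for (int i = 0; i < m; ++i) {
    double r = b[i];
    for (int j = 0; j < nvar; ++j) r -= A(i, j) * tb.val[j];
    resid[i] = r;
  }
  // basis = signed artificial columns so initial artificial values are >= 0
  for (int i = 0; i < m; ++i) {
    int aj = nvar + i;
    tb.lb[aj] = 0.0; tb.ub[aj] = INF;
    tb.basis[i] = aj; tb.state[aj] = 2; tb.val[aj] = 0.0;
  }
  for (int i = 0; i < m; ++i) {
    double s = (resid[i] < 0) ? -1.0 : 1.0;
    for (int j = 0; j < nvar; ++j) tb.at(i, j) = s * A(i, j);
    tb.at(i, nvar + i) = 1.0;
    tb.at(i, n) = s * resid[i];
  }

  std::vector<double> c1(n, 0.0);
  for (int i = 0; i < m; ++i) c1[nvar + i] = 1.0;
  int st = run_simplex(tb, c1, false, eps, max_iter);
  if (st == 3)
    return List::create(_["status"] = 3, _["objective"] = NA_REAL, _["x"] = R_NilValue);
  double infeas = 0.0;
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] >= nvar) infeas += std::abs(tb.at(i, n));
  if (infeas > 1e-7)
    return List::create(_["status"] = 1, _["objective"] = NA_REAL, _["x"] = R_NilValue);
  // lock artificials at zero for phase 2 (basic ones sit at 0 in redundant rows)
  for (int j = nvar; j < n; ++j) {
    tb.ub[j] = 0.0;
    if (tb.state[j] != 2) { tb.state[j] = 0; tb.val[j] = 0.0; }
  }

  std::vector<double> c2(n, 0.0);
  for (int j = 0; j < nvar; ++j) c2[j] = cc[j];
  st = run_simplex(tb, c2, maximize, eps, max_iter);
  if (st != 0)
    return List::create(_["status"] = st, _["objective"] = NA_REAL, _["x"] = R_NilValue);

  NumericVector x(nvar);
  for (int j = 0; j < nvar; ++j)
    x[j] = (tb.state[j] == 2) ? 0.0 : tb.val[j];
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] < nvar) x[tb.basis[i]] = tb.at(i, n);
  double obj = 0.0;
  for (int j = 0; j < nvar; ++j) obj += cc[j] * x[j];
  return List::create(_["status"] = 0, _["objective"] = obj, _["x"] = x);
}

// Solve one feasibility phase, then maximise several objectives in sequence,
// re-using the optimal tableau of each solve as the (feasible) start of the
// next. This is the hot path of the per-sample demand sweep, where only the
// objective indicator changes between solves.
// [[Rcpp::export(name = ".simplex_lp_multi")]]
List simplex_lp_multi(NumericMatrix A, NumericVector b, NumericVector lb,
                      NumericVector ub, IntegerVector obj_cols,
                      bool maximize = true, double eps = 1e-9,
                      int max_iter = 20000) {
  const int m = A.nrow(), nvar = A.ncol(), nobj = obj_cols.size();
  NumericVector objs(nobj, NA_REAL);
  IntegerVector stats(nobj, 1);

  const int n = nvar + m;
  Tableau tb;
  tb.m = m; tb.n = n;
  tb.T.assign((size_t)m * (n + 1), 0.0);
  tb.basis.resize(m);
  tb.state.assign(n, 0);
  tb.lb.resize(n); tb.ub.resize(n); tb.val.resize(n);
  for (int j = 0; j < nvar; ++j) {
    tb.lb[j] = lb[j]; tb.ub[j] = ub[j];
    if (std::isfinite(lb[j])) { tb.state[j] = 0; tb.val[j] = lb[j]; }
    else if (std::isfinite(ub[j])) { tb.state[j] = 1; tb.val[j] = ub[j]; }
    else stop("simplex: column %d has no finite bound", j + 1);
  }
  std::vector<double> resid(m);
  for (int i = 0; i < m; ++i) {
    double r = b[i];
    for (int j = 0; j < nvar; ++j) r -= A(i, j) * tb.val[j];
    resid[i] = r;
  }
  for (int i = 0; i < m; ++i) {
    int aj = nvar + i;
    tb.lb[aj] = 0.0; tb.ub[aj] = INF;
    tb.basis[i] = aj; tb.state[aj] = 2; tb.val[aj] = 0.0;
  }
  for (int i = 0; i < m; ++i) {
    double s = (resid[i] < 0) ? -1.0 : 1.0;
    for (int j = 0; j < nvar; ++j) tb.at(i, j) = s * A(i, j);
    tb.at(i, nvar + i) = 1.0;
    tb.at(i, n) = s * resid[i];
  }
  std::vector<double> c1(n, 0.0);
  for (int i = 0; i < m; ++i) c1[nvar + i] = 1.0;
  int st = run_simplex(tb, c1, false, eps, max_iter);
  if (st == 3)
    return List::create(_["status"] = IntegerVector(nobj, 3),
                        _["objective"] = objs);
  double infeas = 0.0;
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] >= nvar) infeas += std::abs(tb.at(i, n));
  if (infeas > 1e-7)
    return List::create(_["status"] = stats, _["objective"] = objs);
  for (int j = nvar; j < n; ++j) {
    tb.ub[j] = 0.0;
    if (tb.state[j] != 2) { tb.state[j] = 0; tb.val[j] = 0.0; }
  }

  std::vector<double> c2(n, 0.0);
  for (int q = 0; q < nobj; ++q) {
    int oc = obj_cols[q] - 1;  // 1-based from R
    if (oc < 0 || oc >= nvar) stop("objective column out of range");
    std::fill(c2.begin(), c2.begin() + nvar, 0.0);
    c2[oc] = 1.0;
    st = run_simplex(tb, c2, maximize, eps, max_iter);
    stats[q] = st;
    if (st == 0) {
      double x_oc;
      if (tb.state[oc] == 2) {
        x_oc = 0.0;
        for (int i = 0; i < m; ++i)
          if (tb.basis[i] == oc) { x_oc = tb.at(i, n); break; }
      } else {
        x_oc = tb.val[oc];
      }
      objs[q] = x_oc;
    } else if (st != 2) {
      break;  // iteration limit: stop the sweep, remaining stay NA
    }
  }
  return List::create(_["status"] = stats, _["objective"] = objs);
}
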