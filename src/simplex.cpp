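// Bounded-variable two-phase primal simplex for flux balance problems:
//   optimize c'x  s.t.  A x = b,  lb <= x <= ub.
// Dense arithmetic (toy/EC models here have a few hundred columns), explicit
// basis-inverse updates with periodic refactorization, Dantzig pricing with a
// Bland's-rule fallback, a two-pass ratio test preferring large pivots, and a
// residual check that re-solves the whole program under Bland's rule when a
// degenerate pivot path left an ill-conditioned final basis.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BIG = 1e29;
// Pivot admissibility is coarser than optimality pricing: accepting pivot
// elements near the pricing tolerance corrupts the basis inverse and stalls
// phase 1 at false optima.
static const double PIV_TOL = 1e-7;

struct SimplexState {
  mat Af;          // m x (n + m): structural columns then artificials
  vec b, L, U, x;
  uvec basis;      // length m, column indices into Af
  ivec vstat;      // 0 = at lower bound, 1 = at upper bound, 2 = basic
  mat Binv;
  int m, n;
  double tol;
};

// Recompute Binv and basic values from scratch (numerical hygiene).
static bool refactorize(SimplexState &st) {
  mat B(st.m, st.m);
  for (int i = 0; i < st.m; ++i) B.col(i) = st.Af.col(st.basis[i]);
  mat Binv;
  if (!inv(Binv, B)) return false;
  st.Binv = Binv;
  vec xn = st.x;
  for (int i = 0; i < st.m; ++i) xn[st.basis[i]] = 0.0;
  vec r = st.b - st.Af * xn;
  vec xB = st.Binv * r;
  for (int i = 0; i < st.m; ++i) st.x[st.basis[i]] = xB[i];
  return true;
}

// One simplex phase on cost vector cc (minimization).
// Returns 0 optimal, 2 unbounded, 3 iteration limit, 4 numerical failure.
static int run_phase(SimplexState &st, const vec &cc,
                     bool allow_artificial_entry, int maxit,
                     bool bland_start) {
  const int m = st.m, n = st.n, N = st.n + st.m;
  const double tol = st.tol;
  bool bland = bland_start;
  int degen_run = 0, since_refactor = 0;

  for (int iter = 0; iter < maxit; ++iter) {
    vec cB(m);
    for (int i = 0; i < m; ++i) cB[i] = cc[st.basis[i]];
    vec y = st.Binv.t() * cB;

    // pricing
    int q = -1, qdir = 0;
    double best = tol;
    for (int j = 0; j < N; ++j) {
      if (st.vstat[j] == 2) continue;
      if (!allow_artificial_entry && j >= n) continue;
      if (st.U[j] - st.L[j] < tol && st.vstat[j] == 0 && st.L[j] == st.U[j])
        continue; // fixed variable
      double dj = cc[j] - dot(y, st.Af.col(j));
      double viol; int dir;
      if (st.vstat[j] == 0 && dj < -tol)      { viol = -dj; dir = +1; }
      else if (st.vstat[j] == 1 && dj > tol)  { viol =  dj; dir = -1; }
      else continue;
      if (bland) { q = j; qdir = dir; break; }
      if (viol > best) { best = viol; q = j; qdir = dir; }
    }
    if (q < 0) return 0; // optimal

    vec w = st.Binv * st.Af.col(q);

    // two-pass ratio test; basic i moves by -qdir * t * w[i]. Pass 1 finds
    // the minimum ratio; pass 2 picks, among candidates within tolerance of
    // it, the largest pivot magnitude (numerical stability), smallest basis
    // index as the deterministic tie-break (and exclusively under Bland).
    double flip = st.U[q] - st.L[q];
    if (flip > BIG) flip = datum::inf;
    double tmin = flip;
    for (int i = 0; i < m; ++i) {
      double wi = -qdir * w[i];
      double t;
      if (wi > PIV_TOL) {
        double ub_i = st.U[st.basis[i]];
        if (ub_i > BIG) continue;
        t = (ub_i - st.x[st.basis[i]]) / wi;
      } else if (wi < -PIV_TOL) {
        double lb_i = st.L[st.basis[i]];
        if (lb_i < -BIG) continue;
        t = (lb_i - st.x[st.basis[i]]) / wi;
      } else continue;
      if (t < 0.0) t = 0.0;
      if (t < tmin) tmin = t;
    }
    int leave = -1, leave_bnd = 0;
    double tstar = flip;
    if (std::isfinite(tmin)) {
      double best_piv = 0.0;
      for (int i = 0; i < m; ++i) {
        double wi = -qdir * w[i];
        double t;
        int bnd;
        if (wi > PIV_TOL) {
          double ub_i = st.U[st.basis[i]];
          if (ub_i > BIG) continue;
          t = (ub_i - st.x[st.basis[i]]) / wi;
          bnd = 1;
        } else if (wi < -PIV_TOL) {
          double lb_i = st.L[st.basis[i]];
          if (lb_i < -BIG) continue;
          t = (lb_i - st.x[st.basis[i]]) / wi;
          bnd = 0;
        } else continue;
        if (t < 0.0) t = 0.0;
        if (t > tmin + tol) continue;
        double pm = std::abs(wi);
        bool better;
        if (bland) {
          better = (leave < 0 || st.basis[i] < st.basis[leave]);
        } else {
          better = (leave < 0 || pm > best_piv * (1.0 + 1e-9) ||
                    (pm > best_piv * (1.0 - 1e-9) &&
                     st.basis[i] < st.basis[leave]));
        }
        if (better) { leave = i; leave_bnd = bnd; best_piv = pm; }
      }
      if (leave >= 0) tstar = tmin;
    }

    if (!std::isfinite(tstar)) return 2; // unbounded

    if (tstar < tol) ++degen_run; else degen_run = 0;
    if (degen_run > 60) bland = true;

    // apply the step
    for (int i = 0; i < m; ++i)
      st.x[st.basis[i]] += -qdir * tstar * w[i];

    if (leave < 0) {
      // bound flip of the entering variable
      st.x[q] = (qdir > 0) ? st.U[q] : st.L[q];
      st.vstat[q] = (qdir > 0) ? 1 : 0;
      continue;
    }

    st.x[q] = (st.vstat[q] == 0 ? st.L[q] : st.U[q]) + qdir * tstar;
    int out = st.basis[leave];
    st.x[out] = (leave_bnd == 1) ? st.U[out] : st.L[out];
    st.vstat[out] = leave_bnd;
    st.basis[leave] = q;
    st.vstat[q] = 2;

    double piv = w[leave];
    if (std::abs(piv) < PIV_TOL) {
      if (!refactorize(st)) return 4;
      continue;
    }
    rowvec br = st.Binv.row(leave) / piv;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double wi = w[i];
      if (wi != 0.0) st.Binv.row(i) -= wi * br;
    }
    st.Binv.row(leave) = br;

    if (++since_refactor >= 100) {
      if (!refactorize(st)) return 4;
      since_refactor = 0;
    }
  }
  return 3;
}

struct SolveResult {
  std::string status;
  vec x, y, d;
  double obj = NA_REAL;
  double residual = 0.0;
};

static SolveResult solve_once(const mat &A, const vec &b, const vec &cobj,
                              const vec &lb, const vec &ub, bool maximize,
                              double tol, int maxit, bool bland_start) {
  const int m = A.n_rows, n = A.n_cols;
  vec c = maximize ? vec(-cobj) : cobj;
  SolveResult res;
  res.x.zeros(n);
  res.y.zeros(m);
  res.d.zeros(n);

  SimplexState st;
  st.m = m; st.n = n; st.tol = tol;
  st.b = b;
  st.Af.zeros(m, n + m);
  st.Af.cols(0, n - 1) = A;
  st.L.set_size(n + m); st.U.set_size(n + m);
  st.L.head(n) = lb;    st.U.head(n) = ub;
  st.x.zeros(n + m);
  st.vstat.set_size(n + m);

  for (int j = 0; j < n; ++j) {
    double l = lb[j], u = ub[j];
    bool at_lb = std::isfinite(l) &&
      (!std::isfinite(u) || std::abs(l) <= std::abs(u));
    if (!std::isfinite(l) && !std::isfinite(u)) {
      st.x[j] = 0.0; st.vstat[j] = 0; st.L[j] = -BIG * 10;
    } else if (at_lb) { st.x[j] = l; st.vstat[j] = 0; }
    else              { st.x[j] = u; st.vstat[j] = 1; }
  }

  vec r = b - A * st.x.head(n);
  st.basis.set_size(m);
  st.Binv.zeros(m, m);
  for (int i = 0; i < m; ++i) {
    double s = (r[i] >= 0) ? 1.0 : -1.0;
    st.Af(i, n + i) = s;
    st.x[n + i] = std::abs(r[i]);
    st.L[n + i] = 0.0;
    st.U[n + i] = datum::inf;
    st.basis[i] = n + i;
    st.vstat[n + i] = 2;
    st.Binv(i, i) = s;
  }

  // Phase 1: drive artificials to zero
  vec c1(n + m, fill::zeros);
  c1.tail(m).ones();
  int s1 = run_phase(st, c1, true, maxit, bland_start);
  refactorize(st);  // drop accumulated drift before judging feasibility
  double art = 0.0;
  for (int i = 0; i < m; ++i) art += std::abs(st.x[n + i]);
  if (s1 == 4) { res.status = "numerical_failure"; return res; }
  if (s1 == 3) { res.status = "maxit"; return res; }
  if (art > 1e-6 * std::max(1.0, norm(b, "inf"))) {
    res.status = "infeasible";
    return res;
  }

  // pin artificials at zero and run phase 2 on the true objective
  for (int i = 0; i < m; ++i) {
    st.U[n + i] = 0.0;
    if (st.vstat[n + i] != 2) { st.x[n + i] = 0.0; st.vstat[n + i] = 0; }
  }
  vec c2(n + m, fill::zeros);
  c2.head(n) = c;
  int s2 = run_phase(st, c2, false, maxit, bland_start);
  if (s2 == 2) { res.status = "unbounded"; return res; }
  if (s2 == 3) { res.status = "maxit"; return res; }
  if (s2 == 4) { res.status = "numerical_failure"; return res; }

  refactorize(st);
  res.status = "optimal";
  res.x = st.x.head(n);
  for (int j = 0; j < n; ++j) {  // clamp basic-value drift into bounds
    if (res.x[j] < lb[j]) res.x[j] = lb[j];
    if (res.x[j] > ub[j]) res.x[j] = ub[j];
  }
  res.obj = dot(cobj, res.x);
  vec cB(m);
  for (int i = 0; i < m; ++i) cB[i] = c2[st.basis[i]];
  vec y = st.Binv.t() * cB;
  if (maximize) y = -y;
  res.y = y;
  for (int j = 0; j < n; ++j) res.d[j] = cobj[j] - dot(y, A.col(j));
  res.residual = norm(A * res.x - b, "inf");
  return res;
}

//' @noRd
// [[Rcpp::export(name = ".simplex_bounded")]]
Rcpp::List simplex_bounded(const arma::mat &A, const arma::vec &b,
                           const arma::vec &cobj, const arma::vec &lb,
                           const arma::vec &ub, bool maximize,
                           double tol = 1e-9, int maxit = 50000) {
  double acc = 1e-7 * std::max(1.0, norm(b, "inf"));
  SolveResult res = solve_once(A, b, cobj, lb, ub, maximize, tol, maxit,
                               false);
  if (res.status == "maxit" || res.status == "numerical_failure" ||
      (res.status == "optimal" && res.residual > acc)) {
    // deterministic fallback: the degenerate pivot path left an inaccurate
    // or unfinished solve; Bland's rule from the start takes another path
    SolveResult retry = solve_once(A, b, cobj, lb, ub, maximize, tol,
                                   maxit, true);
    if (!(retry.status == "optimal" && retry.residual > acc)) res = retry;
    if (res.status == "optimal" && res.residual > acc) {
      res.status = "numerical_failure";
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("status") = res.status,
      Rcpp::Named("x") = res.x,
      Rcpp::Named("objective") = res.obj,
      Rcpp::Named("dual") = res.y,
      Rcpp::Named("reduced_cost") = res.d,
      Rcpp::Named("residual") = res.residual);
}
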