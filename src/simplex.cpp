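// Dense two-phase revised simplex for box-constrained LPs:
//
//   minimize c'x  subject to  A x = b,  0 <= x <= u   (all u finite)
//
// This is the package's LP engine for FBA/FVA/GIMME. Flux models are
// solved in split (nonnegative-variable) form, so equality rows plus
// upper bounds are the only constraint types needed. Sizes are small
// (tens to low hundreds of columns), so a dense basis factorisation per
// iteration is both simple and numerically safe. Dantzig pricing with a
// switch to Bland's rule after 5(n+m) iterations guarantees termination
// on the highly degenerate LPs that stoichiometric models produce.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double FEAS_TOL = 1e-9;
static const double COST_TOL = 1e-9;

// status codes: 2 basic, 0 nonbasic at lower (0), 1 nonbasic at upper (u)
struct SimplexState {
  uvec basis;               // m basic column indices
  std::vector<int> vstat;   // per-column status
};

static vec current_x(const mat &A, const vec &b, const vec &u,
                     const SimplexState &st) {
  const int n = A.n_cols;
  vec x(n, fill::zeros);
  for (int j = 0; j < n; ++j)
    if (st.vstat[j] == 1) x[j] = u[j];
  vec rhs = b;
  for (int j = 0; j < n; ++j)
    if (st.vstat[j] == 1 && x[j] != 0.0) rhs -= A.col(j) * x[j];
  mat B = A.cols(st.basis);
  vec xb = solve(B, rhs, solve_opts::no_approx);
  for (uword i = 0; i < st.basis.n_elem; ++i) x[st.basis[i]] = xb[i];
  return x;
}

// returns 0 optimal, 2 iteration limit
static int simplex_core(const mat &A, const vec &b, const vec &c,
                        const vec &u, SimplexState &st, int maxit) {
  const int m = A.n_rows, n = A.n_cols;
  const int bland_after = 5 * (n + m);
  for (int iter = 0; iter < maxit; ++iter) {
    bool bland = iter >= bland_after;
    mat B = A.cols(st.basis);
    vec cb(m);
    for (int i = 0; i < m; ++i) cb[i] = c[st.basis[i]];
    vec y = solve(B.t(), cb, solve_opts::no_approx);

    // pricing: nonbasic at lower wants d_j < 0, at upper wants d_j > 0
    int enter = -1, dir = 0;     // dir +1 increase from lower, -1 decrease from upper
    double best = 0.0;
    for (int j = 0; j < n; ++j) {
      if (st.vstat[j] == 2 || u[j] <= FEAS_TOL) continue;
      double dj = c[j] - dot(y, A.col(j));
      double viol = 0.0;
      int d = 0;
      if (st.vstat[j] == 0 && dj < -COST_TOL) { viol = -dj; d = +1; }
      else if (st.vstat[j] == 1 && dj > COST_TOL) { viol = dj; d = -1; }
      else continue;
      if (bland) { enter = j; dir = d; break; }
      if (viol > best) { best = viol; enter = j; dir = d; }
    }
    if (enter < 0) return 0;  // optimal

    vec w = solve(B, vec(A.col(enter)), solve_opts::no_approx);
    vec x = current_x(A, b, u, st);

    // ratio test: entering moves by t >= 0 (in direction dir), basic
    // variables move by -dir * w * t and must stay in [0, u_basic];
    // the entering variable itself may at most traverse its own span.
    double tmax = u[enter];   // full-span move = bound flip, no pivot
    int leave = -1;           // position in basis
    int leave_to = 0;         // 0 -> leaves at lower bound, 1 -> at upper
    for (int i = 0; i < m; ++i) {
      double wi = dir * w[i];
      double xi = x[st.basis[i]];
      double t;
      int to;
      if (wi > FEAS_TOL) { t = xi / wi; to = 0; }
      else if (wi < -FEAS_TOL) { t = (u[st.basis[i]] - xi) / (-wi); to = 1; }
      else continue;
      if (t < 0.0) t = 0.0;
      bool take = false;
      if (t < tmax - FEAS_TOL) take = true;
      else if (leave >= 0 && t <= tmax + FEAS_TOL && bland &&
               st.basis[i] < st.basis[leave]) take = true;
      if (take) {
        tmax = std::min(tmax, t);
        leave = i;
        leave_to = to;
      }
    }

    if (leave < 0) {
      // entering variable flips bound (moves its full span)
      st.vstat[enter] = (dir > 0) ? 1 : 0;
      continue;
    }
    int out = st.basis[leave];
    st.vstat[out] = leave_to;
    st.vstat[enter] = 2;
    st.basis[leave] = enter;
  }
  return 2;
}

// [[Rcpp::export(name = ".simplex_bounded")]]
Rcpp::List simplex_bounded(const arma::mat &A, const arma::vec &b,
                           const arma::vec &c, const arma::vec &u,
                           bool maximize, int maxit) {
  const int m = A.n_rows, n = A.n_cols;
  vec obj = maximize ? vec(-c) : c;

  // phase 1: artificial basis, rows signed so artificial values = |b| >= 0
  mat A1(m, n + m, fill::zeros);
  vec b1 = b;
  A1.cols(0, n - 1) = A;
  for (int i = 0; i < m; ++i) {
    double s = (b[i] < 0.0) ? -1.0 : 1.0;
    if (s < 0) { A1.row(i) *= -1.0; b1[i] = -b[i]; }
    A1(i, n + i) = 1.0;
  }
  double art_cap = std::max(1.0, 2.0 * (norm(b, "inf") + 1.0));
  vec u1(n + m);
  u1.subvec(0, n - 1) = u;
  u1.subvec(n, n + m - 1).fill(art_cap);
  vec c1(n + m, fill::zeros);
  c1.subvec(n, n + m - 1).fill(1.0);

  SimplexState st;
  st.basis = regspace<uvec>(n, n + m - 1);
  st.vstat.assign(n + m, 0);
  for (int i = 0; i < m; ++i) st.vstat[n + i] = 2;

  int maxit1 = maxit > 0 ? maxit : 200 * (n + m);
  int rc = simplex_core(A1, b1, c1, u1, st, maxit1);
  vec x1 = current_x(A1, b1, u1, st);
  double phase1 = 0.0;
  for (int i = 0; i < m; ++i) phase1 += x1[n + i];
  if (rc == 2 || phase1 > 1e-7)
    return Rcpp::List::create(
        Rcpp::Named("status") = (rc == 2 ? 2 : 1),
        Rcpp::Named("x") = Rcpp::NumericVector(n),
        Rcpp::Named("objective") = NA_REAL);

  // phase 2: lock artificials at zero, optimise the real objective
  for (int i = 0; i < m; ++i) u1[n + i] = 0.0;
  vec c2(n + m, fill::zeros);
  c2.subvec(0, n - 1) = obj;
  rc = simplex_core(A1, b1, c2, u1, st, maxit1);
  vec x2 = current_x(A1, b1, u1, st);
  vec x = x2.subvec(0, n - 1);
  // clip solver-tolerance noise back into the box
  for (int j = 0; j < n; ++j) {
    if (x[j] < 0.0 && x[j] > -1e-7) x[j] = 0.0;
    if (x[j] > u[j] && x[j] < u[j] + 1e-7) x[j] = u[j];
  }
  double val = dot(c, x);
  return Rcpp::List::create(
      Rcpp::Named("status") = (rc == 2 ? 2 : 0),
      Rcpp::Named("x") = Rcpp::NumericVector(x.begin(), x.end()),
      Rcpp::Named("objective") = val);
}
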