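// Dense bounded-variable two-phase revised simplex.
//
// Solves   maximize c'x   s.t.  A x = b,  lb <= x <= ub
// and returns primal solution, objective, row duals (y) and reduced
// costs (d), which downstream code uses for shadow prices.  Problem
// sizes here are small (core metabolic models, tens of rows), so the
// basis is refactorised from scratch at every iteration; robustness is
// preferred over speed.  Anti-cycling: Dantzig pricing with a switch to
// Bland's rule after an iteration threshold.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct SimplexState {
  mat Afull;          // m x (n + m), structural + artificial columns
  vec b, lb, ub;      // length n + m
  uvec basis;         // length m, indices into columns of Afull
  ivec stat;          // 0 at lower, 1 at upper, 2 free at zero, 3 basic
  vec x;              // length n + m
  int n, m;
};

// Recompute basic variable values from the nonbasic ones.
bool recompute_basics(SimplexState &S, const mat &B) {
  vec q = S.b;
  for (int j = 0; j < S.n + S.m; ++j) {
    if (S.stat[j] != 3 && S.x[j] != 0.0) q -= S.Afull.col(j) * S.x[j];
  }
  vec xB;
  bool ok = solve(xB, B, q, solve_opts::no_approx);
  if (!ok) return false;
  for (int i = 0; i < S.m; ++i) S.x[S.basis[i]] = xB[i];
  return true;
}

// Core iteration loop.  Returns 0 optimal, 2 unbounded, 3 maxiter,
// 4 singular basis.
int simplex_core(SimplexState &S, const vec &cost, int maxiter, double tol) {
  const int ntot = S.n + S.m;
  const int bland_after = 2000 + 20 * ntot;
  for (int iter = 0; iter < maxiter; ++iter) {
    const bool bland = iter > bland_after;
    mat B = S.Afull.cols(S.basis);
    if (!recompute_basics(S, B)) return 4;
    vec cB(S.m);
    for (int i = 0; i < S.m; ++i) cB[i] = cost[S.basis[i]];
    vec y;
    if (!solve(y, B.t(), cB, solve_opts::no_approx)) return 4;

    // entering variable
    int e = -1, sigma = 0;
    double best = tol;
    for (int j = 0; j < ntot; ++j) {
      if (S.stat[j] == 3) continue;
      double dj = cost[j] - dot(y, S.Afull.col(j));
      double viol = 0.0;
      int sg = 0;
      if (S.stat[j] == 0 && dj > tol) { viol = dj; sg = 1; }
      else if (S.stat[j] == 1 && dj < -tol) { viol = -dj; sg = -1; }
      else if (S.stat[j] == 2 && std::fabs(dj) > tol) {
        viol = std::fabs(dj); sg = dj > 0 ? 1 : -1;
      }
      if (sg != 0) {
        if (bland) { e = j; sigma = sg; break; }
        if (viol > best) { best = viol; e = j; sigma = sg; }
      }
    }
    if (e < 0) return 0;  // optimal

    vec w;
    if (!solve(w, B, S.Afull.col(e), solve_opts::no_approx)) return 4;

    // ratio test: entering moves by t*sigma; basic i moves by -sigma*t*w[i]
    double tmin = INF;
    int leave = -1;        // index into basis; -1 means bound flip of e
    int leave_to = 0;      // 0: leaving hits lower, 1: hits upper
    if (std::isfinite(S.lb[e]) && std::isfinite(S.ub[e]))
      tmin = S.ub[e] - S.lb[e];
    const double ptol = 1e-10;
    for (int i = 0; i < S.m; ++i) {
      double coef = sigma * w[i];
      double xi = S.x[S.basis[i]];
      if (coef > ptol) {
        if (std::isfinite(S.lb[S.basis[i]])) {
          double t = (xi - S.lb[S.basis[i]]) / coef;
          if (t < 0) t = 0;
          if (t < tmin - 1e-12 ||
              (std::fabs(t - tmin) <= 1e-12 &&
               (leave < 0 ? false
                          : (bland ? S.basis[i] < S.basis[leave]
                                   : std::fabs(coef) > std::fabs(sigma * w[leave]))))) {
            tmin = t; leave = i; leave_to = 0;
          }
        }
      } else if (coef < -ptol) {
        if (std::isfinite(S.ub[S.basis[i]])) {
          double t = (S.ub[S.basis[i]] - xi) / (-coef);
          if (t < 0) t = 0;
          if (t < tmin - 1e-12 ||
              (std::fabs(t - tmin) <= 1e-12 &&
               (leave < 0 ? false
                          : (bland ? S.basis[i] < S.basis[leave]
                                   : std::fabs(coef) > std::fabs(sigma * w[leave]))))) {
            tmin = t; leave = i; leave_to = 1;
          }
        }
      }
    }
    if (!std::isfinite(tmin)) return 2;  // unbounded

    if (leave < 0) {
      // bound flip of the entering variable
      S.x[e] = (sigma > 0) ? S.ub[e] : S.lb[e];
      S.stat[e] = (sigma > 0) ? 1 : 0;
    } else {
      uword lv = S.basis[leave];
      double xe_start = S.x[e];
      S.x[e] = xe_start + sigma * tmin;
      S.stat[e] = 3;
      S.x[lv] = (leave_to == 0) ? S.lb[lv] : S.ub[lv];
      S.stat[lv] = (leave_to == 0) ? 0 : 1;
      if (!std::isfinite(S.x[lv])) { S.x[lv] = 0.0; S.stat[lv] = 2; }
      S.basis[leave] = e;
    }
  }
  return 3;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_simplex(const arma::mat &A, const arma::vec &b,
                       const arma::vec &lb, const arma::vec &ub,
                       const arma::vec &obj, bool maximize,
                       double tol = 1e-9, int maxiter = 0) {
  const int m = A.n_rows, n = A.n_cols;
  if (maxiter <= 0) maxiter = 20000 + 200 * (n + m);

  SimplexState S;
  S.n = n; S.m = m;
  S.b = b;
  S.Afull = join_rows(A, eye<mat>(m, m));
  S.lb = vec(n + m);
  S.ub = vec(n + m);
  S.x = zeros<vec>(n + m);
  S.stat = ivec(n + m);
  for (int j = 0; j < n; ++j) {
    S.lb[j] = lb[j]; S.ub[j] = ub[j];
    if (std::isfinite(lb[j]) &&
        (!std::isfinite(ub[j]) || std::fabs(lb[j]) <= std::fabs(ub[j]))) {
      S.x[j] = lb[j]; S.stat[j] = 0;
    } else if (std::isfinite(ub[j])) {
      S.x[j] = ub[j]; S.stat[j] = 1;
    } else {
      S.x[j] = 0.0; S.stat[j] = 2;
    }
  }
  // artificial columns: sign chosen so starting values are nonnegative
  vec r = b;
  for (int j = 0; j < n; ++j)
    if (S.x[j] != 0.0) r -= A.col(j) * S.x[j];
  S.basis = uvec(m);
  for (int i = 0; i < m; ++i) {
    if (r[i] < 0) S.Afull(i, n + i) = -1.0;
    S.basis[i] = n + i;
    S.lb[n + i] = 0.0; S.ub[n + i] = INF;
    S.x[n + i] = std::fabs(r[i]);
    S.stat[n + i] = 3;
  }

  // Phase 1: drive artificials to zero
  vec cost1 = zeros<vec>(n + m);
  for (int i = 0; i < m; ++i) cost1[n + i] = -1.0;
  int st = simplex_core(S, cost1, maxiter, tol);
  double art = 0.0;
  for (int i = 0; i < m; ++i) art += S.x[n + i];
  double scale1 = std::max(1.0, norm(b, "inf"));
  if (st == 4)
    return Rcpp::List::create(Rcpp::Named("status") = 4);
  if (st == 3 || art > 1e-7 * scale1) {
    int code = (st == 3) ? 3 : 1;  // maxiter or infeasible
    return Rcpp::List::create(Rcpp::Named("status") = code,
                              Rcpp::Named("phase1_residual") = art);
  }
  // pin artificials at zero for phase 2
  for (int i = 0; i < m; ++i) { S.ub[n + i] = 0.0; S.x[n + i] = 0.0; }

  // Phase 2
  vec cost2 = zeros<vec>(n + m);
  for (int j = 0; j < n; ++j) cost2[j] = maximize ? obj[j] : -obj[j];
  st = simplex_core(S, cost2, maxiter, tol);
  if (st == 4)
    return Rcpp::List::create(Rcpp::Named("status") = 4);
  if (st == 2)
    return Rcpp::List::create(Rcpp::Named("status") = 2);

  mat B = S.Afull.cols(S.basis);
  recompute_basics(S, B);
  vec cB(m);
  for (int i = 0; i < m; ++i) cB[i] = cost2[S.basis[i]];
  vec y = solve(B.t(), cB, solve_opts::no_approx);
  vec d(n);
  for (int j = 0; j < n; ++j) d[j] = cost2[j] - dot(y, S.Afull.col(j));
  if (!maximize) { y = -y; d = -d; }

  vec xout = S.x.subvec(0, n - 1);
  double objval = dot(obj, xout);
  Rcpp::IntegerVector statout(n);
  for (int j = 0; j < n; ++j) statout[j] = S.stat[j];
  return Rcpp::List::create(
      Rcpp::Named("status") = (st == 3 ? 3 : 0),
      Rcpp::Named("x") = xout,
      Rcpp::Named("obj") = objval,
      Rcpp::Named("y") = y,
      Rcpp::Named("d") = d,
      Rcpp::Named("vstat") = statout);
}

// Exact two-sided permutation p-value for the Spearman correlation of
// two (mid-)rank vectors, by full enumeration of the n! pairings.
// [[Rcpp::export]]
Rcpp::List cpp_spearman_exact(const arma::vec &rx, const arma::vec &ry) {
  const int n = rx.n_elem;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  const double mx = mean(rx), my = mean(ry);
  const double target = std::fabs(dot(rx, ry) - n * mx * my);
  long long count = 0, total = 0;
  std::sort(idx.begin(), idx.end());
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += rx[i] * ry[idx[i]];
    if (std::fabs(s - n * mx * my) >= target - 1e-9) ++count;
    ++total;
  } while (std::next_permutation(idx.begin(), idx.end()));
  return Rcpp::List::create(Rcpp::Named("count") = (double)count,
                            Rcpp::Named("total") = (double)total);
}
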