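#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Solver for the elastic-net objective in its raw residual-sum-of-squares
// form (no 1/n or 1/2 rescaling):
//   f(mu, b) = (y - mu*1 - X b)'(y - mu*1 - X b)
//              + lambda * sum_j [(1-alpha) b_j^2 + alpha |b_j|].
// With l1 = lambda*alpha/2 and l2 = lambda*(1-alpha) the stationarity
// conditions on centered data are
//   x_j'r = l2 b_j + l1 sign(b_j)   for b_j != 0,
//   |x_j'r| <= l1                   for b_j  = 0,
// and the penalty reads l2*sum b^2 + 2*l1*sum|b|. The unpenalized
// intercept is profiled out by centering X and y (mu = ybar - xbar'b).
//
// Per lambda the main engine is feature-sign search: solve the equality-
// constrained system on the working set, take the exact minimizer of f
// along the segment to the solution (evaluating every sign-crossing
// point), drop zeroed coordinates, and add KKT violators until the KKT
// conditions hold. Each step decreases f, coordinates are zeroed exactly,
// and the accepted point is an exact stationary point. Coordinate descent
// (the classic soft-threshold update) provides warm-up sweeps and a
// guaranteed fallback under a sweep budget.

struct EnState {
  int n, m;
  std::vector<double> X;      // centered, column-major
  std::vector<double> xbar;
  std::vector<double> y;      // centered
  double ybar;
  std::vector<double> xx;     // per-column sum of squares
  std::vector<double> xty;    // X'y (centered)
  std::vector<double> G;      // Gram X'X when m is small enough
  bool haveG;
  std::vector<double> b, r;   // coefficients, residual y - X b
};

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One coordinate-descent sweep (all coordinates, or active only).
static double cd_sweep(EnState& st, double l1, double l2, bool full) {
  double maxd = 0.0;
  for (int j = 0; j < st.m; ++j) {
    if (!full && st.b[j] == 0.0) continue;
    const double denom = st.xx[j] + l2;
    if (denom <= 0.0) { st.b[j] = 0.0; continue; }
    const double* xj = &st.X[(size_t)j * st.n];
    double xr = 0.0;
    for (int i = 0; i < st.n; ++i) xr += xj[i] * st.r[i];
    const double z = xr + st.b[j] * st.xx[j];
    const double bn = soft(z, l1) / denom;
    const double d = st.b[j] - bn;
    if (d != 0.0) {
      for (int i = 0; i < st.n; ++i) st.r[i] += xj[i] * d;
      const double ad = std::fabs(d);
      if (ad > maxd) maxd = ad;
    }
    st.b[j] = bn;
  }
  return maxd;
}

static int cd_until(EnState& st, double l1, double l2, double tol,
                    int budget) {
  int sw = 0;
  while (sw < budget) {
    ++sw;
    if (cd_sweep(st, l1, l2, true) < tol) break;
    while (sw < budget) {
      ++sw;
      if (cd_sweep(st, l1, l2, false) < tol) break;
    }
  }
  return sw;
}

// Objective value at the current state.
static double objective(const EnState& st, double l1, double l2) {
  double rss = 0.0;
  for (int i = 0; i < st.n; ++i) rss += st.r[i] * st.r[i];
  double q2 = 0.0, q1 = 0.0;
  for (int j = 0; j < st.m; ++j) {
    q2 += st.b[j] * st.b[j];
    q1 += std::fabs(st.b[j]);
  }
  return rss + l2 * q2 + 2.0 * l1 * q1;
}

// Solve (X_W'X_W + l2 I) b = X_W'y - l1*theta on the working set; Cholesky
// first, SVD-based min-norm least squares when singular (working sets as
// large as n arise for alpha = 1 at small lambda). Returns success.
static bool solve_W(const EnState& st, const std::vector<int>& W,
                    const std::vector<double>& theta, double l1, double l2,
                    std::vector<double>& out) {
  const int q = (int)W.size();
  std::vector<double> H((size_t)q * q);
  out.resize(q);
  for (int a = 0; a < q; ++a) {
    const int ja = W[a];
    out[a] = st.xty[ja] - l1 * theta[a];
    for (int c = 0; c < q; ++c) {
      const int jc = W[c];
      double g;
      if (st.haveG) g = st.G[(size_t)jc * st.m + ja];
      else {
        const double* xa = &st.X[(size_t)ja * st.n];
        const double* xc = &st.X[(size_t)jc * st.n];
        g = 0.0;
        for (int i = 0; i < st.n; ++i) g += xa[i] * xc[i];
      }
      H[(size_t)c * q + a] = g + (a == c ? l2 : 0.0);
    }
  }
  std::vector<double> Hc(H), rhs(out);
  int info = 0, nrhs = 1;
  F77_CALL(dposv)("L", &q, &nrhs, Hc.data(), &q, out.data(), &q,
                  &info FCONE);
  if (info == 0) return true;
  out = rhs;
  int rank = 0, lwork = -1, one_i = 1;
  double rcond = 1e-12, wq = 0.0;
  std::vector<double> sv(q);
  F77_CALL(dgelss)(&q, &q, &one_i, H.data(), &q, out.data(), &q, sv.data(),
                   &rcond, &rank, &wq, &lwork, &info);
  if (info != 0) return false;
  lwork = (int)wq;
  std::vector<double> work(lwork);
  F77_CALL(dgelss)(&q, &q, &one_i, H.data(), &q, out.data(), &q, sv.data(),
                   &rcond, &rank, work.data(), &lwork, &info);
  return info == 0;
}

// Exact minimizer of f along b + t*(bnew - b), t in (0, 1], evaluating
// t = 1 and every sign-crossing point. Updates b and r; zeroes crossing
// coordinates exactly. Returns the new objective value.
static double line_step(EnState& st, const std::vector<int>& W,
                        const std::vector<double>& bnew, double l1, double l2,
                        double f_cur) {
  const int q = (int)W.size();
  std::vector<double> delta(q), u(st.n, 0.0);
  for (int a = 0; a < q; ++a) delta[a] = bnew[a] - st.b[W[a]];
  for (int a = 0; a < q; ++a) {
    const double* xj = &st.X[(size_t)W[a] * st.n];
    const double d = delta[a];
    if (d != 0.0) for (int i = 0; i < st.n; ++i) u[i] += xj[i] * d;
  }
  double ru = 0.0, uu = 0.0, rr = 0.0;
  for (int i = 0; i < st.n; ++i) {
    ru += st.r[i] * u[i];
    uu += u[i] * u[i];
    rr += st.r[i] * st.r[i];
  }
  double sb2 = 0.0, sbd = 0.0, sd2 = 0.0;
  for (int a = 0; a < q; ++a) {
    const double bj = st.b[W[a]];
    sb2 += bj * bj; sbd += bj * delta[a]; sd2 += delta[a] * delta[a];
  }
  // off-set l1 terms outside W are constant along the segment
  double l1_off = 0.0;
  {
    double tot = 0.0;
    for (int j = 0; j < st.m; ++j) tot += std::fabs(st.b[j]);
    for (int a = 0; a < q; ++a) tot -= std::fabs(st.b[W[a]]);
    l1_off = tot;
  }
  std::vector<double> cand;
  cand.push_back(1.0);
  for (int a = 0; a < q; ++a) {
    const double bj = st.b[W[a]];
    if (delta[a] != 0.0 && bj != 0.0) {
      const double tc = -bj / delta[a];
      if (tc > 1e-14 && tc < 1.0) cand.push_back(tc);
    }
  }
  double best_t = 0.0, best_f = f_cur;
  for (double t : cand) {
    double l1s = l1_off;
    for (int a = 0; a < q; ++a) l1s += std::fabs(st.b[W[a]] + t * delta[a]);
    const double f = (rr - 2.0 * t * ru + t * t * uu) +
      l2 * (sb2 + 2.0 * t * sbd + t * t * sd2) + 2.0 * l1 * l1s;
    if (f < best_f - 1e-14) { best_f = f; best_t = t; }
  }
  if (best_t == 0.0) return f_cur;  // no descent along this segment
  for (int a = 0; a < q; ++a) {
    double nb = st.b[W[a]] + best_t * delta[a];
    if (st.b[W[a]] != 0.0 && delta[a] != 0.0) {
      const double tc = -st.b[W[a]] / delta[a];
      if (std::fabs(tc - best_t) < 1e-12) nb = 0.0;  // crossing: exact zero
    }
    st.b[W[a]] = nb;
  }
  for (int i = 0; i < st.n; ++i) st.r[i] -= best_t * u[i];
  return best_f;
}

// [[Rcpp::export]]
List en_path_cpp(NumericMatrix Xin, NumericVector yin, NumericVector lambdas,
                 double alpha, double tol, int max_sweeps) {
  EnState st;
  st.n = Xin.nrow(); st.m = Xin.ncol();
  const int n = st.n, m = st.m, L = lambdas.size();
  st.X.resize((size_t)n * m); st.xbar.resize(m); st.y.resize(n);
  st.xx.resize(m); st.xty.resize(m);
  st.b.assign(m, 0.0);
  st.ybar = 0.0;
  for (int i = 0; i < n; ++i) st.ybar += yin[i];
  st.ybar /= n;
  for (int i = 0; i < n; ++i) st.y[i] = yin[i] - st.ybar;
  for (int j = 0; j < m; ++j) {
    double mu = 0.0;
    for (int i = 0; i < n; ++i) mu += Xin(i, j);
    mu /= n;
    st.xbar[j] = mu;
    double ss = 0.0, sy = 0.0;
    double* xj = &st.X[(size_t)j * n];
    for (int i = 0; i < n; ++i) {
      xj[i] = Xin(i, j) - mu;
      ss += xj[i] * xj[i];
      sy += xj[i] * st.y[i];
    }
    st.xx[j] = ss; st.xty[j] = sy;
  }
  st.haveG = (size_t)m <= 4000;
  if (st.haveG) {
    st.G.assign((size_t)m * m, 0.0);
    const double one = 1.0, zero = 0.0;
    F77_CALL(dsyrk)("L", "T", &m, &n, &one, st.X.data(), &n, &zero,
                    st.G.data(), &m FCONE FCONE);
    for (int j = 0; j < m; ++j)
      for (int i = j + 1; i < m; ++i)
        st.G[(size_t)i * m + j] = st.G[(size_t)j * m + i];
  }
  st.r = st.y;

  NumericMatrix B(m, L);
  NumericVector Mu(L);
  IntegerVector iters_used(L);
  std::vector<double> grad(m), bnew;
  std::vector<int> W;
  std::vector<double> theta;

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    const double l1 = lam * alpha / 2.0;
    const double l2 = lam * (1.0 - alpha);
    const double kkt_eps = 1e-9 * std::max(1.0, l1);
    bool done = false;
    int it = 0, stalls = 0;
    double f_cur = objective(st, l1, l2);
    double f_outer = f_cur;
    W.clear(); theta.clear();
    for (int j = 0; j < m; ++j)
      if (st.b[j] != 0.0) { W.push_back(j); theta.push_back(st.b[j] > 0 ? 1 : -1); }
    while (it < 400) {
      ++it;
      // descend on the current working set until a full step is taken
      int inner = 0;
      while (!W.empty() && inner++ < 60) {
        for (size_t a = 0; a < W.size(); ++a)
          if (st.b[W[a]] != 0.0) theta[a] = st.b[W[a]] > 0 ? 1.0 : -1.0;
        if (!solve_W(st, W, theta, l1, l2, bnew)) break;
        const double f_new = line_step(st, W, bnew, l1, l2, f_cur);
        const bool progress = f_new < f_cur - 1e-12 * (1.0 + std::fabs(f_cur));
        f_cur = f_new;
        // drop exact zeros from the working set
        size_t k = 0;
        for (size_t a = 0; a < W.size(); ++a)
          if (st.b[W[a]] != 0.0 || theta[a] == 0.0) {
            W[k] = W[a]; theta[k] = theta[a]; ++k;
          }
        W.resize(k); theta.resize(k);
        if (!progress) break;
      }
      // KKT scan: stationarity on W, violations elsewhere
      double worst_v = 0.0;
      int worst_j = -1;
      bool stationary = true;
      std::vector<std::pair<double, int> > viols;
      for (int j = 0; j < m; ++j) {
        const double* xj = &st.X[(size_t)j * n];
        double xr = 0.0;
        for (int i = 0; i < n; ++i) xr += xj[i] * st.r[i];
        grad[j] = xr;
        if (st.b[j] != 0.0) {
          const double dev = std::fabs(xr - l2 * st.b[j] -
                                       l1 * (st.b[j] > 0 ? 1.0 : -1.0));
          if (dev > kkt_eps * 10.0 + 1e-9) stationary = false;
        } else if (std::fabs(xr) > l1 + kkt_eps) {
          viols.push_back(std::make_pair(std::fabs(xr), j));
          if (std::fabs(xr) > worst_v) { worst_v = std::fabs(xr); worst_j = j; }
        }
      }
      (void)worst_j;
      if (stationary && viols.empty()) { done = true; break; }
      if (f_cur >= f_outer - 1e-12 * (1.0 + std::fabs(f_outer))) {
        if (++stalls >= 3) break;  // no descent: hand over to plain CD
      } else stalls = 0;
      f_outer = f_cur;
      if (!viols.empty()) {
        std::sort(viols.rbegin(), viols.rend());
        const int add = std::min((int)viols.size(), 8);
        for (int a = 0; a < add; ++a) {
          const int j = viols[a].second;
          W.push_back(j);
          theta.push_back(grad[j] > 0 ? 1.0 : -1.0);
        }
      } else {
        // stationarity off but no violators: polish with CD and continue
        cd_sweep(st, l1, l2, true);
        f_cur = objective(st, l1, l2);
        W.clear(); theta.clear();
        for (int j = 0; j < m; ++j)
          if (st.b[j] != 0.0) { W.push_back(j); theta.push_back(st.b[j] > 0 ? 1 : -1); }
      }
    }
    if (!done) it += cd_until(st, l1, l2, tol, max_sweeps);
    for (int j = 0; j < m; ++j) B(j, l) = st.b[j];
    double mu = st.ybar;
    for (int j = 0; j < m; ++j) mu -= st.xbar[j] * st.b[j];
    Mu[l] = mu;
    iters_used[l] = it;
  }
  return List::create(_["beta"] = B, _["intercept"] = Mu,
                      _["sweeps"] = iters_used);
}
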