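// Parametric-bootstrap machinery for the correlated-evolution (Pagel) test:
// simulation of trait pairs under a fitted independent model and fast
// refitting of both models per replicate. Uses R's RNG so results follow
// set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat pagel_Q_from_lograates(const arma::vec& lr, bool indep) {
  arma::vec r(8);
  if (indep) {
    r = {std::exp(lr(0)), std::exp(lr(0)), std::exp(lr(1)), std::exp(lr(1)),
         std::exp(lr(2)), std::exp(lr(2)), std::exp(lr(3)), std::exp(lr(3))};
  } else {
    for (int i = 0; i < 8; ++i) r(i) = std::exp(lr(i));
  }
  arma::mat Q(4, 4, arma::fill::zeros);
  // states 1..4 = 00,01,10,11 (x first, y second); r as documented in R
  Q(0, 2) = r(0); Q(1, 3) = r(1); Q(2, 0) = r(2); Q(3, 1) = r(3);
  Q(0, 1) = r(4); Q(2, 3) = r(5); Q(1, 0) = r(6); Q(3, 2) = r(7);
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

static arma::vec stationary4(const arma::mat& Q) {
  arma::mat A(5, 4);
  A.rows(0, 3) = Q.t();
  A.row(4).ones();
  arma::vec b(5, arma::fill::zeros);
  b(4) = 1.0;
  arma::vec p = arma::solve(A, b);
  p.elem(arma::find(p < 0)).zeros();
  return p / arma::accu(p);
}

// pruning lnL with per-unique-branch-length P caching; the propagators are
// built from one eigendecomposition of Q (falling back to expmat if the
// eigenproblem is defective)
static double pagel_lnL_fast(const arma::mat& tippart, const arma::imat& edge,
                             const arma::vec& tlen, const arma::uvec& tgroup,
                             const arma::mat& Q, const arma::vec& pivec,
                             std::vector<arma::mat>& Pcache,
                             const arma::vec& tuniq) {
  arma::cx_vec lam;
  arma::cx_mat V;
  bool ok = arma::eig_gen(lam, V, Q);
  arma::cx_mat Vinv;
  if (ok) ok = arma::inv(Vinv, V);
  if (ok) {
    for (arma::uword k = 0; k < tuniq.n_elem; ++k) {
      arma::cx_mat P = V * arma::diagmat(arma::exp(lam * tuniq(k))) * Vinv;
      Pcache[k] = arma::real(P);
      Pcache[k].elem(arma::find(Pcache[k] < 0)).zeros();
    }
  } else {
    for (arma::uword k = 0; k < tuniq.n_elem; ++k) {
      Pcache[k] = arma::expmat(Q * tuniq(k));
    }
  }
  const arma::uword n_tips = tippart.n_cols;
  const arma::uword n_edges = edge.n_rows;
  arma::uword max_id = n_tips;
  for (arma::uword e = 0; e < n_edges; ++e)
    max_id = std::max(max_id, (arma::uword)edge(e, 0));
  std::vector<arma::vec> part(max_id + 1);
  std::vector<double> logsc(max_id + 1, 0.0);
  std::vector<bool> init(max_id + 1, false);
  const arma::uword root = edge(n_edges - 1, 0);
  for (arma::uword e = 0; e < n_edges; ++e) {
    const arma::uword p = edge(e, 0), c = edge(e, 1);
    const arma::mat& P = Pcache[tgroup(e)];
    arma::vec contrib = (c <= n_tips) ? arma::vec(P * tippart.col(c - 1))
                                      : arma::vec(P * part[c]);
    if (!init[p]) { part[p] = arma::vec(4, arma::fill::ones); init[p] = true; }
    part[p] %= contrib;
    if (c > n_tips) logsc[p] += logsc[c];
    double m = part[p].max();
    if (m > 0) { part[p] /= m; logsc[p] += std::log(m); }
  }
  double lik = arma::dot(pivec, part[root]);
  return std::log(std::max(lik, 1e-300)) + logsc[root];
}

struct PagelObj {
  const arma::mat& tippart;
  const arma::imat& edge;
  const arma::vec& tlen;
  const arma::uvec& tgroup;
  const arma::vec& tuniq;
  bool indep;
  bool root_stationary;
  double lb, ub;
  mutable std::vector<arma::mat> Pcache;
  PagelObj(const arma::mat& tp, const arma::imat& ed, const arma::vec& tl,
           const arma::uvec& tg, const arma::vec& tu, bool ind, bool rs,
           double lo, double hi)
      : tippart(tp), edge(ed), tlen(tl), tgroup(tg), tuniq(tu), indep(ind),
        root_stationary(rs), lb(lo), ub(hi), Pcache(tu.n_elem) {}
  double operator()(arma::vec x) const {
    x = arma::clamp(x, lb, ub);
    arma::mat Q = pagel_Q_from_lograates(x, indep);
    arma::vec pivec = root_stationary ? stationary4(Q)
                                      : arma::vec(4, arma::fill::value(0.25));
    double ll = pagel_lnL_fast(tippart, edge, tlen, tgroup, Q, pivec, Pcache,
                               tuniq);
    return std::isfinite(ll) ? -ll : 1e10;
  }
};

// compact Nelder-Mead with box clamping on the parameters
static double nelder_mead(const PagelObj& f, arma::vec& x, int maxit,
                          double ftol) {
  const arma::uword n = x.n_elem;
  arma::mat S(n, n + 1);
  arma::vec fv(n + 1);
  S.col(0) = x;
  fv(0) = f(x);
  for (arma::uword i = 0; i < n; ++i) {
    arma::vec xi = x;
    xi(i) += 0.4;
    S.col(i + 1) = xi;
    fv(i + 1) = f(xi);
  }
  for (int it = 0; it < maxit; ++it) {
    arma::uvec ord = arma::sort_index(fv);
    S = S.cols(ord); fv = fv(ord);
    if (fv(n) - fv(0) < ftol) break;
    arma::vec centroid = arma::mean(S.cols(0, n - 1), 1);
    arma::vec xr = centroid + (centroid - S.col(n));
    double fr = f(xr);
    if (fr < fv(0)) {
      arma::vec xe = centroid + 2.0 * (centroid - S.col(n));
      double fe = f(xe);
      if (fe < fr) { S.col(n) = xe; fv(n) = fe; }
      else { S.col(n) = xr; fv(n) = fr; }
    } else if (fr < fv(n - 1)) {
      S.col(n) = xr; fv(n) = fr;
    } else {
      arma::vec xc = centroid + 0.5 * (S.col(n) - centroid);
      double fc = f(xc);
      if (fc < fv(n)) { S.col(n) = xc; fv(n) = fc; }
      else {
        for (arma::uword i = 1; i <= n; ++i) {
          S.col(i) = S.col(0) + 0.5 * (S.col(i) - S.col(0));
          fv(i) = f(S.col(i));
        }
      }
    }
  }
  arma::uword best = fv.index_min();
  x = arma::clamp(S.col(best), f.lb, f.ub);
  return fv(best);
}

// Nelder-Mead with fresh-simplex restarts from the incumbent, so fits
// converge to the same quality regardless of starting point
static double nm_restarts(const PagelObj& f, arma::vec& x, int maxit,
                          double ftol, int rounds) {
  double best = nelder_mead(f, x, maxit, ftol);
  for (int r = 1; r < rounds; ++r) {
    arma::vec x2 = x;
    double f2 = nelder_mead(f, x2, maxit, ftol);
    if (f2 < best - 1e-12) { best = f2; x = x2; } else break;
  }
  return best;
}

// Fit one Pagel model by Nelder-Mead on log rates.
// [[Rcpp::export]]
List pagel_fit_nm_cpp(const arma::mat& tippart, const arma::imat& edge,
                      const arma::vec& tlen, bool indep,
                      const arma::mat& starts, bool root_stationary,
                      double lb, double ub, int maxit = 600,
                      double ftol = 1e-8) {
  arma::vec tuniq = arma::unique(tlen);
  arma::uvec tgroup(tlen.n_elem);
  for (arma::uword e = 0; e < tlen.n_elem; ++e)
    tgroup(e) = arma::index_min(arma::abs(tuniq - tlen(e)));
  PagelObj obj(tippart, edge, tlen, tgroup, tuniq, indep, root_stationary,
               lb, ub);
  double bestf = 1e11;
  arma::vec bestx;
  for (arma::uword s = 0; s < starts.n_cols; ++s) {
    arma::vec x = starts.col(s);
    double fx = nm_restarts(obj, x, maxit, ftol, 3);
    if (fx < bestf) { bestf = fx; bestx = x; }
  }
  return List::create(_["lnL"] = -bestf, _["lograates"] = bestx);
}

// Parametric bootstrap of the LRT under the independent model.
// gen_lograates: generating independent-model log rates (length 4).
// Returns the simulated LRT statistics.
// [[Rcpp::export]]
arma::vec pagel_bootstrap_cpp(const arma::imat& edge, const arma::vec& tlen,
                              int n_tips, const arma::vec& gen_lograates,
                              bool root_stationary, int n_sim,
                              double lb, double ub, int maxit = 400,
                              double ftol = 1e-7) {
  const arma::uword n_edges = edge.n_rows;
  arma::mat Qg = pagel_Q_from_lograates(gen_lograates, true);
  arma::vec pivec = root_stationary ? stationary4(Qg)
                                    : arma::vec(4, arma::fill::value(0.25));
  // generating-model transition matrices, fixed across replicates
  std::vector<arma::mat> Pg(n_edges);
  for (arma::uword e = 0; e < n_edges; ++e) Pg[e] = arma::expmat(Qg * tlen(e));

  arma::uword max_id = n_tips;
  for (arma::uword e = 0; e < n_edges; ++e)
    max_id = std::max(max_id, (arma::uword)edge(e, 0));
  const arma::uword root = edge(n_edges - 1, 0);

  arma::vec tuniq = arma::unique(tlen);
  arma::uvec tgroup(tlen.n_elem);
  for (arma::uword e = 0; e < tlen.n_elem; ++e)
    tgroup(e) = arma::index_min(arma::abs(tuniq - tlen(e)));

  arma::vec stats(n_sim);
  RNGScope scope;
  arma::vec dep_start0(8);
  dep_start0 = {gen_lograates(0), gen_lograates(0), gen_lograates(1),
                gen_lograates(1), gen_lograates(2), gen_lograates(2),
                gen_lograates(3), gen_lograates(3)};

  for (int r = 0; r < n_sim; ++r) {
    // simulate states preorder (reverse postorder); the observed test is
    // conditioned on both traits being polymorphic, so redraw replicates
    // until they are too
    arma::ivec state(max_id + 1);
    bool poly = false;
    for (int attempt = 0; attempt < 1000 && !poly; ++attempt) {
      {
        double u = R::runif(0, 1), acc = 0;
        int st = 3;
        for (int k = 0; k < 4; ++k) { acc += pivec(k); if (u <= acc) { st = k; break; } }
        state(root) = st;
      }
      for (arma::sword e = n_edges - 1; e >= 0; --e) {
        const arma::uword p = edge(e, 0), c = edge(e, 1);
        const arma::mat& P = Pg[e];
        double u = R::runif(0, 1), acc = 0;
        int st = 3;
        for (int k = 0; k < 4; ++k) { acc += P(state(p), k); if (u <= acc) { st = k; break; } }
        state(c) = st;
      }
      bool anyx0 = false, anyx1 = false, anyy0 = false, anyy1 = false;
      for (int i = 0; i < n_tips; ++i) {
        int st = state(i + 1);
        if (st >= 2) anyx1 = true; else anyx0 = true;
        if (st == 1 || st == 3) anyy1 = true; else anyy0 = true;
      }
      poly = anyx0 && anyx1 && anyy0 && anyy1;
    }
    if (!poly) { stats(r) = 0.0; continue; }
    arma::mat tp(4, n_tips, arma::fill::zeros);
    for (int i = 0; i < n_tips; ++i) tp(state(i + 1), i) = 1.0;

    PagelObj oi(tp, edge, tlen, tgroup, tuniq, true, root_stationary, lb, ub);
    arma::vec xi = gen_lograates;
    double fi = nm_restarts(oi, xi, maxit, ftol, 2);
    PagelObj od(tp, edge, tlen, tgroup, tuniq, false, root_stationary, lb, ub);
    arma::vec xd(8);
    xd = {xi(0), xi(0), xi(1), xi(1), xi(2), xi(2), xi(3), xi(3)};
    double fd = nm_restarts(od, xd, maxit, ftol, 2);
    stats(r) = std::max(0.0, 2.0 * (fi - fd));
  }
  return stats;
}
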