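// Likelihood kernels: Felsenstein pruning over a codon state space with a
// finite mixture of rate matrices, and a 4-state joint chain for pairs of
// binary traits. Trees must be supplied as postorder edge lists (children
// before parents), 1-based node ids with tips 1..n_tips.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-class, per-site log-likelihoods for a mixture of reversible rate
// matrices supplied in eigen form: P_q(t) = A_q diag(exp(lam_q t)) B_q.
// tipstate: n_tips x n_sites integer states in 1..n (0 = missing: partial
// likelihood 1 over all states). qmap: n_edges x n_classes, 1-based index
// into the eigen slices (allows branch-specific matrices, e.g. clade models).
// [[Rcpp::export]]
arma::mat mixture_pruning_loglik_cpp(const arma::imat& tipstate,
                                     const arma::imat& edge,
                                     const arma::vec& tlen,
                                     const arma::cube& A,
                                     const arma::cube& B,
                                     const arma::mat& lam,
                                     const arma::imat& qmap,
                                     const arma::vec& pivec) {
  const arma::uword n = A.n_rows;
  const arma::uword n_sites = tipstate.n_cols;
  const arma::uword n_tips = tipstate.n_rows;
  const arma::uword n_edges = edge.n_rows;
  const arma::uword n_classes = qmap.n_cols;
  const arma::uword n_nodes = n_tips + n_edges + 1 - n_tips; // tips + internals
  // number of nodes = max node id; compute robustly
  arma::uword max_id = n_tips;
  for (arma::uword e = 0; e < n_edges; ++e) {
    max_id = std::max(max_id, (arma::uword)edge(e, 0));
    max_id = std::max(max_id, (arma::uword)edge(e, 1));
  }
  (void)n_nodes;

  arma::mat out(n_classes, n_sites);
  const arma::uword root = edge(n_edges - 1, 0); // parent of last postorder edge

  // transition matrices cached per unique (generator, branch length) pair
  std::map<std::pair<int, double>, arma::mat> Pcache;
  auto getP = [&](int q, double t) -> const arma::mat& {
    auto key = std::make_pair(q, t);
    auto it = Pcache.find(key);
    if (it != Pcache.end()) return it->second;
    arma::mat P = A.slice(q) * arma::diagmat(arma::exp(lam.col(q) * t)) * B.slice(q);
    P.elem(arma::find(P < 0)).zeros(); // clip tiny negatives from roundoff
    return Pcache.emplace(key, std::move(P)).first->second;
  };

  for (arma::uword cl = 0; cl < n_classes; ++cl) {
    std::vector<arma::mat> part(max_id + 1);
    std::vector<arma::rowvec> logsc(max_id + 1);
    std::vector<bool> init(max_id + 1, false);

    for (arma::uword e = 0; e < n_edges; ++e) {
      const arma::uword p = edge(e, 0);
      const arma::uword c = edge(e, 1);
      const int q = qmap(e, cl) - 1;
      const arma::mat& P = getP(q, tlen(e));

      if (!init[p]) {
        part[p] = arma::mat(n, n_sites, arma::fill::ones);
        logsc[p] = arma::rowvec(n_sites, arma::fill::zeros);
        init[p] = true;
      }

      if (c <= n_tips) {
        const arma::vec onesv(n, arma::fill::ones);
        for (arma::uword s = 0; s < n_sites; ++s) {
          const int st = tipstate(c - 1, s);
          if (st > 0) {
            part[p].col(s) %= P.col(st - 1);
          } // missing: multiply by rowsums(P) = 1, a no-op
        }
        (void)onesv;
      } else {
        part[p] %= P * part[c];
        logsc[p] += logsc[c];
        part[c].reset();
      }
      // rescale parent to avoid underflow
      arma::rowvec m = arma::max(part[p], 0);
      m.elem(arma::find(m <= 0)).ones();
      part[p].each_row() /= m;
      logsc[p] += arma::log(m);
    }

    arma::rowvec sitelik = pivec.t() * part[root];
    for (arma::uword s = 0; s < n_sites; ++s) {
      out(cl, s) = std::log(std::max(sitelik(s), 1e-300)) + logsc[root](s);
    }
  }
  return out;
}

// Build the eigen structures (A, B, lam with P(t) = A exp(lam t) B) for a
// set of GY94 generators sharing kappa and pi but differing in omega.
// diffmask: 61x61 integer, 1 where codons differ at exactly one position;
// tsmask/nsmask: transition / nonsynonymous indicators on those pairs.
// [[Rcpp::export]]
Rcpp::List codon_eigen_set_cpp(double kappa, const arma::vec& omegas,
                               const arma::vec& pivec,
                               const arma::imat& diffmask,
                               const arma::imat& tsmask,
                               const arma::imat& nsmask) {
  const arma::uword n = pivec.n_elem;
  const arma::uword nQ = omegas.n_elem;
  arma::cube A(n, n, nQ), B(n, n, nQ);
  arma::mat lam(n, nQ);
  arma::vec rates(nQ);
  arma::vec sq = arma::sqrt(pivec);
  arma::mat base(n, n, arma::fill::zeros);
  arma::mat nsfac(n, n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = 0; j < n; ++j) {
      if (i == j || diffmask(i, j) == 0) continue;
      double r = pivec(j);
      if (tsmask(i, j)) r *= kappa;
      base(i, j) = r;
      nsfac(i, j) = nsmask(i, j) ? 1.0 : 0.0;
    }
  }
  for (arma::uword q = 0; q < nQ; ++q) {
    arma::mat Q = base;
    Q.elem(arma::find(nsfac > 0.5)) *= omegas(q);
    Q.diag() = -arma::sum(Q, 1);
    rates(q) = -arma::dot(pivec, Q.diag());
    arma::mat S = arma::diagmat(sq) * Q * arma::diagmat(1.0 / sq);
    S = (S + S.t()) / 2.0;
    arma::vec ev;
    arma::mat U;
    arma::eig_sym(ev, U, S);
    A.slice(q) = arma::diagmat(1.0 / sq) * U;
    B.slice(q) = U.t() * arma::diagmat(sq);
    lam.col(q) = ev;
  }
  return Rcpp::List::create(Rcpp::_["A"] = A, Rcpp::_["B"] = B,
                            Rcpp::_["lam"] = lam, Rcpp::_["rates"] = rates);
}

// Log-likelihood of two binary traits under a 4-state joint chain.
// tippart: 4 x n_tips partial-likelihood columns (handles missing states).
// [[Rcpp::export]]
double four_state_pruning_loglik_cpp(const arma::mat& tippart,
                                     const arma::imat& edge,
                                     const arma::vec& tlen,
                                     const arma::mat& Q,
                                     const arma::vec& pivec) {
  const arma::uword n_tips = tippart.n_cols;
  const arma::uword n_edges = edge.n_rows;
  arma::uword max_id = n_tips;
  for (arma::uword e = 0; e < n_edges; ++e) {
    max_id = std::max(max_id, (arma::uword)edge(e, 0));
    max_id = std::max(max_id, (arma::uword)edge(e, 1));
  }
  std::vector<arma::vec> part(max_id + 1);
  std::vector<double> logsc(max_id + 1, 0.0);
  std::vector<bool> init(max_id + 1, false);
  const arma::uword root = edge(n_edges - 1, 0);

  for (arma::uword e = 0; e < n_edges; ++e) {
    const arma::uword p = edge(e, 0);
    const arma::uword c = edge(e, 1);
    arma::mat P = arma::expmat(Q * tlen(e));
    P.elem(arma::find(P < 0)).zeros();
    arma::vec contrib;
    if (c <= n_tips) {
      contrib = P * tippart.col(c - 1);
    } else {
      contrib = P * part[c];
    }
    if (!init[p]) {
      part[p] = arma::vec(4, arma::fill::ones);
      init[p] = true;
    }
    part[p] %= contrib;
    if (c > n_tips) logsc[p] += logsc[c];
    double m = part[p].max();
    if (m > 0 && (m < 1e-200 || m > 1e200)) {
      part[p] /= m;
      logsc[p] += std::log(m);
    }
  }
  double lik = arma::dot(pivec, part[root]);
  return std::log(std::max(lik, 1e-300)) + logsc[root];
}
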