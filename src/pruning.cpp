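// Felsenstein pruning over a reversible amino-acid model with a discrete
// rate mixture (gamma categories + optional invariant-site spike).
//
// Trees arrive as an edge matrix in postorder (every edge below a node is
// listed before the edge above it), 1-based node indices, tips 1..ntip.
// Transition matrices are built from a cached eigendecomposition of Q:
// P(t) = U diag(exp(lambda * t)) Uinv.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat pmat(const arma::mat& U, const arma::mat& Uinv,
                      const arma::vec& eval, double t) {
  arma::mat P = U * arma::diagmat(arma::exp(eval * t)) * Uinv;
  // eigendecomposition round-off can leave tiny negative entries
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_pmat(const arma::mat& U, const arma::mat& Uinv,
                   const arma::vec& eval, double t) {
  return pmat(U, Uinv, eval, t);
}

// states: ntip x nsites integer matrix, 0-based state codes, -1 = missing.
// Returns per-site log-likelihoods; optionally the root partials per rate
// category (for marginal ancestral reconstruction).
// [[Rcpp::export]]
List cpp_pruning(const IntegerMatrix& edge, const NumericVector& blen,
                 int ntip, int nnode, int root,
                 const IntegerMatrix& states,
                 const arma::mat& U, const arma::mat& Uinv,
                 const arma::vec& eval, const arma::vec& pi,
                 const arma::vec& rates, const arma::vec& weights,
                 double pinv, bool return_root) {
  const int ns = U.n_rows;           // number of states
  const int nsites = states.ncol();
  const int ncat = rates.n_elem;
  const int nedge = edge.nrow();

  arma::mat sitelog_cat(nsites, ncat);          // log L_c(site), scaled
  arma::cube rootpart;                          // ns x nsites x ncat
  arma::mat rootscale;                          // nsites x ncat (log scalers)
  if (return_root) {
    rootpart.set_size(ns, nsites, ncat);
    rootscale.set_size(nsites, ncat);
  }

  // tip partials are category-independent
  arma::cube tippart(ns, nsites, ntip);
  for (int tp = 0; tp < ntip; ++tp) {
    for (int s = 0; s < nsites; ++s) {
      int st = states(tp, s);
      if (st < 0) {
        tippart.slice(tp).col(s).ones();
      } else {
        tippart.slice(tp).col(s).zeros();
        tippart(st, s, tp) = 1.0;
      }
    }
  }

  for (int c = 0; c < ncat; ++c) {
    arma::cube part(ns, nsites, nnode, arma::fill::ones);
    for (int tp = 0; tp < ntip; ++tp) part.slice(tp) = tippart.slice(tp);
    arma::mat logscale(nsites, nnode - ntip, arma::fill::zeros);

    for (int e = 0; e < nedge; ++e) {
      int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      arma::mat P = pmat(U, Uinv, eval, blen[e] * rates[c]);
      part.slice(p) %= (P * part.slice(ch));
      if (ch >= ntip)  // child's accumulated scaler flows to the parent
        logscale.col(p - ntip) += logscale.col(ch - ntip);
      // rescale the parent to dodge underflow on deep trees
      arma::rowvec m = arma::max(part.slice(p), 0);
      for (int s = 0; s < nsites; ++s) {
        if (m[s] > 0.0 && m[s] < 1e-80) {
          part.slice(p).col(s) /= m[s];
          logscale(s, p - ntip) += std::log(m[s]);
        }
      }
    }

    const int r = root - 1;
    arma::rowvec lik = pi.t() * part.slice(r);
    for (int s = 0; s < nsites; ++s) {
      double l = lik[s];
      sitelog_cat(s, c) = (l > 0.0 ? std::log(l) : -1e300) + logscale(s, r - ntip);
    }
    if (return_root) {
      rootpart.slice(c) = part.slice(r);
      rootscale.col(c) = logscale.col(r - ntip);
    }
  }

  // invariant-site component: L_inv(site) = pi[a] if all observed states
  // equal a, 1 if the whole column is missing, else 0
  arma::vec loginv(nsites);
  if (pinv > 0.0) {
    for (int s = 0; s < nsites; ++s) {
      int seen = -2;  // -2 none yet, -1 conflict
      for (int tp = 0; tp < ntip; ++tp) {
        int st = states(tp, s);
        if (st < 0) continue;
        if (seen == -2) seen = st;
        else if (seen != st) { seen = -1; break; }
      }
      if (seen == -1) loginv[s] = -arma::datum::inf;
      else if (seen == -2) loginv[s] = 0.0;
      else loginv[s] = std::log(pi[seen]);
    }
  }

  // combine mixture components with log-sum-exp
  NumericVector sitelik(nsites);
  double total = 0.0;
  for (int s = 0; s < nsites; ++s) {
    double mx = -arma::datum::inf;
    std::vector<double> terms;
    terms.reserve(ncat + 1);
    for (int c = 0; c < ncat; ++c) {
      double t = std::log((1.0 - pinv) * weights[c]) + sitelog_cat(s, c);
      terms.push_back(t);
      if (t > mx) mx = t;
    }
    if (pinv > 0.0) {
      double t = std::log(pinv) + loginv[s];
      terms.push_back(t);
      if (t > mx) mx = t;
    }
    double acc = 0.0;
    for (double t : terms) acc += std::exp(t - mx);
    sitelik[s] = mx + std::log(acc);
    total += sitelik[s];
  }

  List out = List::create(_["sitelik"] = sitelik, _["loglik"] = total,
                          _["sitelog_cat"] = wrap(sitelog_cat));
  if (return_root) {
    out["root_partials"] = wrap(rootpart);
    out["root_logscale"] = wrap(rootscale);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Two-pass (down/up partial) machinery: for every edge, flanking partial
// vectors such that the tree likelihood as a function of that one branch
// length alone is a cheap inner product. Used for fast exact single-edge
// branch-length proposals (and NNI candidate scoring).

static arma::vec log_invariant(const IntegerMatrix& states,
                               const arma::vec& pi, int nsites, int ntip) {
  arma::vec loginv(nsites);
  for (int s = 0; s < nsites; ++s) {
    int seen = -2;
    for (int tp = 0; tp < ntip; ++tp) {
      int st = states(tp, s);
      if (st < 0) continue;
      if (seen == -2) seen = st;
      else if (seen != st) { seen = -1; break; }
    }
    if (seen == -1) loginv[s] = -arma::datum::inf;
    else if (seen == -2) loginv[s] = 0.0;
    else loginv[s] = std::log(pi[seen]);
  }
  return loginv;
}

// Golden-section maximization of a function over log-branch-length.
template <typename F>
static double golden_max(F f, double lo, double hi, int iters, double* fbest) {
  const double gr = 0.6180339887498949;
  double a = std::log(lo), b = std::log(hi);
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = f(std::exp(x1)), f2 = f(std::exp(x2));
  for (int i = 0; i < iters; ++i) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = f(std::exp(x2));
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = f(std::exp(x1));
    }
  }
  double x = (f1 > f2) ? x1 : x2;
  *fbest = std::max(f1, f2);
  return std::exp(x);
}

// For each requested edge row (0-based), propose the branch length
// maximizing the likelihood with all other branches fixed, together with
// the exact tree log-likelihood at that proposal.
// [[Rcpp::export]]
List cpp_edge_proposals(const IntegerMatrix& edge, const NumericVector& blen,
                        int ntip, int nnode, int root,
                        const IntegerMatrix& states,
                        const arma::mat& U, const arma::mat& Uinv,
                        const arma::vec& eval, const arma::vec& pi,
                        const arma::vec& rates, const arma::vec& weights,
                        double pinv, const IntegerVector& rows,
                        double min_bl, double max_bl, int iters) {
  const int ns = U.n_rows;
  const int nsites = states.ncol();
  const int ncat = rates.n_elem;
  const int nedge = edge.nrow();
  const int nreq = rows.size();

  // children edge rows per node
  std::vector<std::vector<int>> kids(nnode);
  for (int e = 0; e < nedge; ++e) kids[edge(e, 0) - 1].push_back(e);

  arma::vec loginv = (pinv > 0.0)
    ? log_invariant(states, pi, nsites, ntip) : arma::vec();

  // flanks per requested edge per category, plus per-site log scalers
  arma::cube fU(ns, nsites, nreq * ncat), fD(ns, nsites, nreq * ncat);
  arma::mat fsc(nsites, nreq * ncat, arma::fill::zeros);

  for (int c = 0; c < ncat; ++c) {
    arma::cube D(ns, nsites, nnode, arma::fill::ones);
    arma::cube E(ns, nsites, nedge);
    arma::mat lsD(nsites, nnode, arma::fill::zeros);
    for (int tp = 0; tp < ntip; ++tp)
      for (int s = 0; s < nsites; ++s) {
        int st = states(tp, s);
        if (st >= 0) { D.slice(tp).col(s).zeros(); D(st, s, tp) = 1.0; }
      }
    for (int e = 0; e < nedge; ++e) {
      int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      arma::mat P = pmat(U, Uinv, eval, blen[e] * rates[c]);
      E.slice(e) = P * D.slice(ch);
      D.slice(p) %= E.slice(e);
      lsD.col(p) += lsD.col(ch);
      arma::rowvec m = arma::max(D.slice(p), 0);
      for (int s = 0; s < nsites; ++s)
        if (m[s] > 0.0 && m[s] < 1e-80) {
          D.slice(p).col(s) /= m[s];
          lsD(s, p) += std::log(m[s]);
        }
    }
    // upward messages, edges in preorder (reverse postorder)
    arma::cube M(ns, nsites, nnode);
    arma::mat lsM(nsites, nnode, arma::fill::zeros);
    M.slice(root - 1).each_col() = pi;
    arma::cube Uv(ns, nsites, nedge);
    arma::mat lsU(nsites, nedge, arma::fill::zeros);
    for (int e = nedge - 1; e >= 0; --e) {
      int p = edge(e, 0) - 1, v = edge(e, 1) - 1;
      Uv.slice(e) = M.slice(p);
      lsU.col(e) = lsM.col(p);
      for (int s_e : kids[p]) {
        if (s_e == e) continue;
        Uv.slice(e) %= E.slice(s_e);
        lsU.col(e) += lsD.col(edge(s_e, 1) - 1);
      }
      if (v >= ntip) {
        arma::mat P = pmat(U, Uinv, eval, blen[e] * rates[c]);
        M.slice(v) = P.t() * Uv.slice(e);
        lsM.col(v) = lsU.col(e);
        arma::rowvec m = arma::max(M.slice(v), 0);
        for (int s = 0; s < nsites; ++s)
          if (m[s] > 0.0 && m[s] < 1e-80) {
            M.slice(v).col(s) /= m[s];
            lsM(s, v) += std::log(m[s]);
          }
      }
    }
    for (int q = 0; q < nreq; ++q) {
      int e = rows[q];
      fU.slice(q * ncat + c) = Uv.slice(e);
      fD.slice(q * ncat + c) = D.slice(edge(e, 1) - 1);
      fsc.col(q * ncat + c) = lsU.col(e) + lsD.col(edge(e, 1) - 1);
    }
  }

  // conditional log-likelihood of branch length t on requested edge q
  auto cond_loglik = [&](int q, double t) {
    arma::mat sitecat(nsites, ncat);
    for (int c = 0; c < ncat; ++c) {
      arma::mat P = pmat(U, Uinv, eval, t * rates[c]);
      arma::mat A = P * fD.slice(q * ncat + c);
      arma::rowvec s = arma::sum(fU.slice(q * ncat + c) % A, 0);
      for (int i = 0; i < nsites; ++i) {
        double l = s[i];
        sitecat(i, c) = (l > 0.0 ? std::log(l) : -1e300) +
          fsc(i, q * ncat + c);
      }
    }
    double total = 0.0;
    for (int s = 0; s < nsites; ++s) {
      double mx = -arma::datum::inf;
      for (int c = 0; c < ncat; ++c) {
        double term = std::log((1.0 - pinv) * weights[c]) + sitecat(s, c);
        sitecat(s, c) = term;
        if (term > mx) mx = term;
      }
      double inv_term = -arma::datum::inf;
      if (pinv > 0.0) {
        inv_term = std::log(pinv) + loginv[s];
        if (inv_term > mx) mx = inv_term;
      }
      double acc = 0.0;
      for (int c = 0; c < ncat; ++c) acc += std::exp(sitecat(s, c) - mx);
      if (pinv > 0.0) acc += std::exp(inv_term - mx);
      total += mx + std::log(acc);
    }
    return total;
  };

  NumericVector prop(nreq), condll(nreq);
  for (int q = 0; q < nreq; ++q) {
    double fbest;
    double t = golden_max([&](double x) { return cond_loglik(q, x); },
                          min_bl, max_bl, iters, &fbest);
    double fcur = cond_loglik(q, blen[rows[q]]);
    if (fcur >= fbest) { t = blen[rows[q]]; fbest = fcur; }
    prop[q] = t;
    condll[q] = fbest;
  }
  return List::create(_["t"] = prop, _["loglik"] = condll);
}
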