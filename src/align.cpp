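// Affine-gap alignment dynamic programming (Gotoh three-state recursion).
// A gap of length L costs open + L * extend (NCBI convention, so the first
// gap residue pays open + extend). Sequences are 0-based indices into the
// scoring matrix; profile-profile alignment scores a column pair as the
// expected substitution score under the two frequency columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double NEG = -1e30;

// path codes: 1 = diagonal, 2 = consume a (gap in b), 3 = consume b (gap in a)
static List dp_align(const arma::mat& sigma, double go, double ge, bool local) {
  const int n = sigma.n_rows, m = sigma.n_cols;
  arma::mat M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  arma::Mat<unsigned char> tbM(n + 1, m + 1, arma::fill::zeros),
      tbX(n + 1, m + 1, arma::fill::zeros), tbY(n + 1, m + 1, arma::fill::zeros);
  M.fill(NEG); X.fill(NEG); Y.fill(NEG);
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) { X(i, 0) = local ? NEG : -(go + i * ge); tbX(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { Y(0, j) = local ? NEG : -(go + j * ge); tbY(0, j) = 3; }
  if (local) for (int i = 0; i <= n; ++i) for (int j = 0; j <= m; ++j) M(i, j) = 0.0;

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: align i with j
      double dM = M(i - 1, j - 1), dX = X(i - 1, j - 1), dY = Y(i - 1, j - 1);
      double mx = dM; unsigned char tb = 1;
      if (dX > mx) { mx = dX; tb = 2; }
      if (dY > mx) { mx = dY; tb = 3; }
      double val = mx + sigma(i - 1, j - 1);
      if (local && val < 0.0) { val = 0.0; tb = 0; }
      M(i, j) = val; tbM(i, j) = tb;
      // X: gap in b (consume a_i)
      double oM = M(i - 1, j) - go - ge, oX = X(i - 1, j) - ge, oY = Y(i - 1, j) - go - ge;
      mx = oM; tb = 1;
      if (oX > mx) { mx = oX; tb = 2; }
      if (oY > mx) { mx = oY; tb = 3; }
      X(i, j) = mx; tbX(i, j) = tb;
      // Y: gap in a (consume b_j)
      double pM = M(i, j - 1) - go - ge, pX = X(i, j - 1) - go - ge, pY = Y(i, j - 1) - ge;
      mx = pM; tb = 1;
      if (pX > mx) { mx = pX; tb = 2; }
      if (pY > mx) { mx = pY; tb = 3; }
      Y(i, j) = mx; tbY(i, j) = tb;
      if (local && M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  int ei, ej, state;  // state 1 = M, 2 = X, 3 = Y
  double score;
  if (local) {
    score = best; ei = bi; ej = bj; state = 1;
    if (best <= 0.0) {  // no positive-scoring segment pair
      return List::create(_["score"] = 0.0, _["path"] = IntegerVector(0),
                          _["a_start"] = 0, _["b_start"] = 0, _["empty"] = true);
    }
  } else {
    double sM = M(n, m), sX = X(n, m), sY = Y(n, m);
    score = sM; state = 1;
    if (sX > score) { score = sX; state = 2; }
    if (sY > score) { score = sY; state = 3; }
    ei = n; ej = m;
  }

  std::vector<int> path;
  int i = ei, j = ej;
  while (true) {
    if (!local && i == 0 && j == 0) break;
    if (local && state == 1 && M(i, j) == 0.0) break;  // local alignment start
    if (state == 1) {
      unsigned char tb = tbM(i, j);
      path.push_back(1); --i; --j;
      if (local && tb == 0) break;  // this cell restarted the segment
      state = tb;
    } else if (state == 2) {
      unsigned char tb = tbX(i, j);
      path.push_back(2); --i; state = tb;
    } else {
      unsigned char tb = tbY(i, j);
      path.push_back(3); --j; state = tb;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score, _["path"] = wrap(path),
                      _["a_start"] = i + 1, _["b_start"] = j + 1,
                      _["empty"] = false);
}

// [[Rcpp::export]]
List cpp_pairwise(const IntegerVector& a, const IntegerVector& b,
                  const NumericMatrix& S, double go, double ge, bool local) {
  arma::mat sigma(a.size(), b.size());
  for (int i = 0; i < a.size(); ++i)
    for (int j = 0; j < b.size(); ++j)
      sigma(i, j) = S(a[i], b[j]);
  return dp_align(sigma, go, ge, local);
}

// f1, f2: nstate x L frequency profiles (columns sum to <= 1; gap mass
// simply contributes no score)
// [[Rcpp::export]]
List cpp_profile_align(const arma::mat& f1, const arma::mat& f2,
                       const arma::mat& S, double go, double ge) {
  arma::mat sigma = f1.t() * S * f2;
  return dp_align(sigma, go, ge, false);
}
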