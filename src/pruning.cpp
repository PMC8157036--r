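#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Matrix exponential (Pade scaling-and-squaring via Armadillo).
// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double t) {
  return arma::expmat(Q * t);
}

// Felsenstein pruning log-likelihood for a k-state CTMC on a rooted tree.
//
// edge:       E x 2 integer matrix (1-based ape node numbering), rows in
//             postorder (every child row precedes its parent's row).
// elen:       branch durations aligned with edge rows.
// n_tip:      number of tips; tips are nodes 1..n_tip.
// tip_state:  per-tip state in 1..k (0 = ambiguous/uniform).
// Q:          k x k rate matrix (rows sum to 0).
// pi:         root state distribution (length k).
//
// Conditional likelihoods are rescaled per node; returns -Inf for
// impossible data (e.g. conflicting states across zero-length branches).
// [[Rcpp::export]]
double cpp_pruning_loglik(const arma::imat& edge, const arma::vec& elen,
                          int n_tip, const arma::ivec& tip_state,
                          const arma::mat& Q, const arma::vec& pi) {
  const int k = Q.n_rows;
  const int n_node = edge.max();
  arma::mat L(n_node, k, arma::fill::ones);
  for (int i = 0; i < n_tip; ++i) {
    int s = tip_state[i];
    if (s > 0) {
      L.row(i).zeros();
      L(i, s - 1) = 1.0;
    }
  }
  // Diagonalize Q once so each branch needs only a reconstruction,
  // P(t) = V exp(D t) V^-1, instead of a full Pade expm. Fall back to
  // expmat per branch when the eigenbasis is ill-conditioned.
  bool use_eig = false;
  arma::cx_vec eigval;
  arma::cx_mat V, Vinv;
  if (arma::eig_gen(eigval, V, Q)) {
    double rc = arma::rcond(V);
    if (rc > 1e-8 && arma::inv(Vinv, V)) use_eig = true;
  }
  double logscale = 0.0;
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int p = edge(e, 0) - 1;
    const int c = edge(e, 1) - 1;
    arma::mat P;
    if (elen[e] == 0.0) {
      P.eye(k, k);
    } else if (use_eig) {
      P = arma::real(V * arma::diagmat(arma::exp(eigval * elen[e])) * Vinv);
      P.clamp(0.0, arma::datum::inf);  // clear tiny negative roundoff
    } else {
      P = arma::expmat(Q * elen[e]);
    }
    arma::rowvec contrib = (P * L.row(c).t()).t();
    L.row(p) %= contrib;
    const double m = L.row(p).max();
    if (m <= 0.0) return R_NegInf;
    L.row(p) /= m;
    logscale += std::log(m);
  }
  const int root = edge(edge.n_rows - 1, 0) - 1;
  const double lik = arma::dot(pi, L.row(root).t());
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + logscale;
}
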