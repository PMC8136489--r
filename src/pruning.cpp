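// Felsenstein pruning over the 61 sense-codon states, batched over the
// mixture categories of a site-class model. Reversibility of GY94 lets each
// category's transition matrices come from one symmetric eigendecomposition.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Per-pattern, per-category site log-likelihoods.
//
// tips:  n_tip x n_pattern integer matrix, codon state 1..61, 0 = missing/gap
// edges: n_edge x 2 integer matrix (parent, child), 1-based node ids in
//        postorder (children appear before their parent edge); root is the
//        parent of the last edge
// blens: branch length per edge (expected substitutions per codon site)
// qcube: 61 x 61 x n_cat scaled generator matrices
// pi:    61 equilibrium frequencies (shared across categories)
//
// returns n_pattern x n_cat matrix of log-likelihoods
// [[Rcpp::export]]
arma::mat site_loglik_mix(const arma::imat& tips, const arma::imat& edges,
                          const arma::vec& blens, const arma::cube& qcube,
                          const arma::vec& pi) {
  const uword n_state = pi.n_elem;
  const uword n_tip = tips.n_rows;
  const uword n_pat = tips.n_cols;
  const uword n_edge = edges.n_rows;
  const uword n_cat = qcube.n_slices;
  const uword n_node = (uword) edges.max();
  const uword root = (uword) edges(n_edge - 1, 0) - 1;

  vec sq = sqrt(pi);
  mat out(n_pat, n_cat);

  for (uword c = 0; c < n_cat; ++c) {
    // symmetrised eigendecomposition of the reversible generator
    mat B = diagmat(sq) * qcube.slice(c) * diagmat(1.0 / sq);
    B = 0.5 * (B + B.t());
    vec vals; mat V;
    eig_sym(vals, V, B);
    mat left = diagmat(1.0 / sq) * V;
    mat right = V.t() * diagmat(sq);

    // transition matrix per edge, with an appended all-ones column so that a
    // missing tip state (index n_state) contributes a flat partial
    std::vector<mat> P(n_edge);
    for (uword e = 0; e < n_edge; ++e) {
      mat Pe = left * diagmat(exp(vals * blens(e))) * right;
      Pe.clamp(0.0, datum::inf);
      Pe.insert_cols(n_state, ones<mat>(n_state, 1));
      P[e] = Pe;
    }

    std::vector<mat> part(n_node);
    std::vector<bool> seen(n_node, false);
    rowvec logscale(n_pat, fill::zeros);

    for (uword e = 0; e < n_edge; ++e) {
      uword p = (uword) edges(e, 0) - 1;
      uword ch = (uword) edges(e, 1) - 1;
      mat T;
      if (ch < n_tip) {
        uvec idx(n_pat);
        for (uword k = 0; k < n_pat; ++k) {
          int s = tips(ch, k);
          idx(k) = (s > 0) ? (uword)(s - 1) : n_state;
        }
        T = P[e].cols(idx);
      } else {
        T = P[e].cols(0, n_state - 1) * part[ch];
        part[ch].reset();
      }
      if (!seen[p]) { part[p] = T; seen[p] = true; }
      else          { part[p] %= T; }

      // rescale underflowing columns of the parent partial
      rowvec cmax = max(part[p], 0);
      for (uword k = 0; k < n_pat; ++k) {
        if (cmax(k) > 0 && cmax(k) < 1e-120) {
          part[p].col(k) *= 1e120;
          logscale(k) -= 120.0 * std::log(10.0);
        }
      }
    }

    rowvec lik = pi.t() * part[root];
    out.col(c) = (log(lik) + logscale).t();
  }
  return out;
}
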