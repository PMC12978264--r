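// R-facing wrapper around the canonical graph builder.
#include "nn_core.h"

using namespace arma;

// q: 3 x N DWI positions, b, e: per-DWI b-values and normalised signals.
// Returns the canonically ordered mirrored k-NN graph (edges 1-based).
// [[Rcpp::export]]
Rcpp::List cpp_build_qgraph(const arma::mat& q, const arma::vec& b,
                            const arma::vec& e, int k) {
  ng::QGraphC g = ng::build_qgraph(q, b, e, k);
  arma::umat edges(g.dst.n_elem, 2);
  edges.col(0) = g.dst + 1;
  edges.col(1) = g.src + 1;
  return Rcpp::List::create(
      Rcpp::Named("positions") = arma::mat(g.pos.t()),
      Rcpp::Named("b") = g.bnode,
      Rcpp::Named("E") = g.enode,
      Rcpp::Named("edges") = edges,
      Rcpp::Named("edge_features") = arma::mat(g.efeat.t()),
      Rcpp::Named("node_features") = arma::mat(g.nfeat.t()));
}
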