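// Rotation/permutation-invariant message-passing network.
//
// Layer 1 messages take [x_j; e_ij] (5 inputs), later layers take x_j only;
// messages are mean-aggregated over neighbours and node states updated via
// [x_i; mbar_i] MLPs; attention-weighted pooling gives a 16-dim embedding,
// read out to (NDI, ODI, FWF). Backprop is written by hand; weights live in
// a flat double vector with the block layout defined in R (gnn_layout()).
#include "nn_core.h"

using namespace arma;
using ng::Mlp;
using ng::Example;

namespace {

struct GnnNet {
  Mlp e1, n1, e2, n2, e3, n3, attn, readout;
};

Mlp mlp3(ng::Reader& r, uword in) {
  Mlp m;
  m.layers = {r.linear(64, in), r.linear(64, 64), r.linear(16, 64)};
  m.acts = {ng::Act::SiLU, ng::Act::SiLU, ng::Act::Linear};
  return m;
}

GnnNet unpack_gnn(const vec& w) {
  ng::Reader r(w);
  GnnNet net;
  net.e1 = mlp3(r, 5);
  net.n1 = mlp3(r, 18);
  net.e2 = mlp3(r, 16);
  net.n2 = mlp3(r, 32);
  net.e3 = mlp3(r, 16);
  net.n3 = mlp3(r, 32);
  net.attn.layers = {r.linear(16, 16), r.linear(1, 16)};
  net.attn.acts = {ng::Act::SiLU, ng::Act::Linear};
  net.readout.layers = {r.linear(32, 16), r.linear(3, 32)};
  net.readout.acts = {ng::Act::SiLU, ng::Act::Linear};
  r.done();
  return net;
}

struct GnnGrad {
  ng::MlpGrad e1, n1, e2, n2, e3, n3, attn, readout;
  void write(ng::Writer& w) {
    e1.write(w); n1.write(w); e2.write(w); n2.write(w);
    e3.write(w); n3.write(w); attn.write(w); readout.write(w);
  }
};

struct FwdCache {
  Mlp::Cache ce1, cn1, ce2, cn2, ce3, cn3, cattn, cro;
  fmat X0, X1, X2, X3;
  vec deg;
  fvec wsoft;
  fvec z;
};

fmat scatter_mean(const fmat& msg, const uvec& dst, uword M, const vec& deg) {
  fmat out(msg.n_rows, M, fill::zeros);
  for (uword e = 0; e < dst.n_elem; ++e) out.col(dst[e]) += msg.col(e);
  for (uword i = 0; i < M; ++i) out.col(i) /= (float)deg[i];
  return out;
}

fmat gather_scale(const fmat& dMbar, const uvec& dst, const vec& deg) {
  fmat out(dMbar.n_rows, dst.n_elem);
  for (uword e = 0; e < dst.n_elem; ++e)
    out.col(e) = dMbar.col(dst[e]) / (float)deg[dst[e]];
  return out;
}

fvec gnn_forward_one(const GnnNet& net, const ng::QGraphC& g, FwdCache& c) {
  uword M = g.nfeat.n_cols, E = g.dst.n_elem;
  c.X0 = conv_to<fmat>::from(g.nfeat);
  fmat ef = conv_to<fmat>::from(g.efeat);
  c.deg.zeros(M);
  for (uword e = 0; e < E; ++e) c.deg[g.dst[e]] += 1.0;

  fmat H1(5, E);
  H1.rows(0, 1) = c.X0.cols(g.src);
  H1.rows(2, 4) = ef;
  fmat mbar1 = scatter_mean(net.e1.forward(H1, c.ce1), g.dst, M, c.deg);
  c.X1 = net.n1.forward(join_cols(c.X0, mbar1), c.cn1);

  fmat mbar2 = scatter_mean(net.e2.forward(c.X1.cols(g.src), c.ce2), g.dst, M, c.deg);
  c.X2 = net.n2.forward(join_cols(c.X1, mbar2), c.cn2);

  fmat mbar3 = scatter_mean(net.e3.forward(c.X2.cols(g.src), c.ce3), g.dst, M, c.deg);
  c.X3 = net.n3.forward(join_cols(c.X2, mbar3), c.cn3);

  fmat scores = net.attn.forward(c.X3, c.cattn);  // 1 x M
  fvec s = scores.row(0).t();
  fvec w = arma::exp(s - s.max());
  w /= arma::accu(w);
  c.wsoft = w;
  c.z = c.X3 * w;
  fmat out = net.readout.forward(fmat(c.z), c.cro);  // 3 x 1
  return out.col(0);
}

void gnn_backward_one(const GnnNet& net, const ng::QGraphC& g,
                      const FwdCache& c, const fvec& dtheta, GnnGrad& G) {
  uword M = g.nfeat.n_cols;
  fmat dz = net.readout.backward(fmat(dtheta), c.cro, G.readout.gW, G.readout.gb);

  // attention pooling: z = X3 w,  w = softmax(attn(X3))
  fmat dX3 = dz * c.wsoft.t();
  fvec dzc = dz.col(0);
  float zdot = arma::dot(c.z, dzc);
  fmat ds(1, M);
  for (uword i = 0; i < M; ++i)
    ds(0, i) = c.wsoft[i] * (arma::dot(c.X3.col(i), dzc) - zdot);
  dX3 += net.attn.backward(ds, c.cattn, G.attn.gW, G.attn.gb);

  // layer 3
  fmat dU3 = net.n3.backward(dX3, c.cn3, G.n3.gW, G.n3.gb);
  fmat dX2 = dU3.rows(0, 15);
  fmat dXsrc = net.e3.backward(gather_scale(dU3.rows(16, 31), g.dst, c.deg),
                               c.ce3, G.e3.gW, G.e3.gb);
  for (uword e = 0; e < g.src.n_elem; ++e) dX2.col(g.src[e]) += dXsrc.col(e);

  // layer 2
  fmat dU2 = net.n2.backward(dX2, c.cn2, G.n2.gW, G.n2.gb);
  fmat dX1 = dU2.rows(0, 15);
  dXsrc = net.e2.backward(gather_scale(dU2.rows(16, 31), g.dst, c.deg),
                          c.ce2, G.e2.gW, G.e2.gb);
  for (uword e = 0; e < g.src.n_elem; ++e) dX1.col(g.src[e]) += dXsrc.col(e);

  // layer 1 (input features are data; their gradient is discarded)
  fmat dU1 = net.n1.backward(dX1, c.cn1, G.n1.gW, G.n1.gb);
  net.e1.backward(gather_scale(dU1.rows(2, 17), g.dst, c.deg),
                  c.ce1, G.e1.gW, G.e1.gb);
}

ng::QGraphC graph_from_observed(const Example& ex, int k) {
  mat qd; vec bd, ed;
  ng::normalise_split(ex, ex.s, qd, bd, ed);
  return ng::build_qgraph(qd, bd, ed, k);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_gnn_predict(const arma::vec& w, Rcpp::List voxels, int k) {
  GnnNet net = unpack_gnn(w);
  uword n = voxels.size();
  mat theta(n, 3), Z(n, 16);
  for (uword i = 0; i < n; ++i) {
    Example ex = ng::example_from_list(voxels[i]);
    FwdCache c;
    fvec th = gnn_forward_one(net, graph_from_observed(ex, k), c);
    theta.row(i) = conv_to<rowvec>::from(th.t());
    Z.row(i) = conv_to<rowvec>::from(c.z.t());
  }
  return Rcpp::List::create(Rcpp::Named("theta") = theta, Rcpp::Named("z") = Z);
}

// Forward pass on a prebuilt graph (edges 1-based, columns dst, src).
// [[Rcpp::export]]
Rcpp::List cpp_gnn_forward_graph(const arma::vec& w,
                                 const arma::mat& node_features,
                                 const arma::umat& edges,
                                 const arma::mat& edge_features) {
  GnnNet net = unpack_gnn(w);
  ng::QGraphC g;
  g.nfeat = node_features.t();
  g.efeat = edge_features.t();
  g.dst = edges.col(0) - 1;
  g.src = edges.col(1) - 1;
  FwdCache c;
  fvec th = gnn_forward_one(net, g, c);
  return Rcpp::List::create(
      Rcpp::Named("theta") = conv_to<vec>::from(th),
      Rcpp::Named("z") = conv_to<vec>::from(c.z));
}

// Loss and analytic gradient on one observed voxel (for gradient checking).
// [[Rcpp::export]]
Rcpp::List cpp_gnn_loss_grad(const arma::vec& w, Rcpp::List voxel, int k,
                             const arma::vec& target) {
  GnnNet net = unpack_gnn(w);
  Example ex = ng::example_from_list(voxel);
  ng::QGraphC g = graph_from_observed(ex, k);
  FwdCache c;
  fvec th = gnn_forward_one(net, g, c);
  fvec tgt = conv_to<fvec>::from(target);
  fvec resid = th - tgt;
  double loss = arma::accu(arma::square(conv_to<vec>::from(resid))) / 3.0;
  GnnGrad G;
  gnn_backward_one(net, g, c, resid * (2.0f / 3.0f), G);
  vec grad(w.n_elem, fill::zeros);
  ng::Writer wr(grad);
  G.write(wr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss, Rcpp::Named("grad") = grad);
}

// One training epoch: grouped batches with gradient accumulation, fresh
// Rician noise (per-batch SNR) and measurement dropout per presentation,
// Adam update with global-norm clipping after each group.
// groups: list of B x P integer matrices (1-based example indices);
// column t of a group is batch t, all columns share parameter sets.
// [[Rcpp::export]]
Rcpp::List cpp_gnn_epoch(const arma::vec& w_in, const arma::vec& m_in,
                         const arma::vec& v_in, int t_in,
                         Rcpp::List examples, Rcpp::List groups,
                         Rcpp::List conf) {
  int k = Rcpp::as<int>(conf["k"]);
  double lr = Rcpp::as<double>(conf["lr"]);
  double clip = Rcpp::as<double>(conf["clip"]);
  double snr_lo = Rcpp::as<double>(conf["snr_lo"]);
  double snr_hi = Rcpp::as<double>(conf["snr_hi"]);
  double drop_p = Rcpp::as<double>(conf["drop_p"]);
  double drop_lo = Rcpp::as<double>(conf["drop_lo"]);
  double drop_hi = Rcpp::as<double>(conf["drop_hi"]);

  std::vector<Example> exs(examples.size());
  for (int i = 0; i < examples.size(); ++i)
    exs[i] = ng::example_from_list(examples[i]);

  vec w = w_in;
  ng::Adam adam;
  adam.m = m_in; adam.v = v_in; adam.t = t_in;

  double loss_sum = 0;
  uword n_seen = 0;
  for (int gi = 0; gi < groups.size(); ++gi) {
    Rcpp::IntegerMatrix gm = groups[gi];
    uword B = gm.nrow(), P = gm.ncol();
    GnnNet net = unpack_gnn(w);
    GnnGrad G;
    float scale = 2.0f / (3.0f * B * P);
    for (uword p = 0; p < P; ++p) {
      double snr = snr_lo + (snr_hi - snr_lo) * unif_rand();
      for (uword r = 0; r < B; ++r) {
        const Example& ex0 = exs[gm(r, p) - 1];
        Example ex = ng::apply_dropout(ex0, drop_p, drop_lo, drop_hi);
        vec sig = ng::rician(ex.s, snr);
        mat qd; vec bd, ed;
        ng::normalise_split(ex, sig, qd, bd, ed);
        ng::QGraphC g = ng::build_qgraph(qd, bd, ed, k);
        FwdCache c;
        fvec th = gnn_forward_one(net, g, c);
        fvec resid = th - conv_to<fvec>::from(ex0.theta);
        loss_sum += arma::accu(arma::square(conv_to<vec>::from(resid))) / 3.0;
        ++n_seen;
        gnn_backward_one(net, g, c, resid * scale, G);
      }
    }
    vec grad(w.n_elem, fill::zeros);
    ng::Writer wr(grad);
    G.write(wr);
    adam.step(w, grad, lr, clip);
  }
  return Rcpp::List::create(
      Rcpp::Named("w") = w, Rcpp::Named("m") = adam.m,
      Rcpp::Named("v") = adam.v, Rcpp::Named("t") = (int)adam.t,
      Rcpp::Named("loss") = loss_sum / std::max<uword>(n_seen, 1));
}
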