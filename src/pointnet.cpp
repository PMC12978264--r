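// Point-set baseline: a PointNet-style network over mirrored q-space points
// with features (qx, qy, qz, E, b). Input and feature transform blocks
// (T-nets) are initialised to the identity; batch normalisation is omitted.
// Permutation-invariant via max-pooling but not rotation-invariant, since
// raw coordinates enter the per-point encoder.
//
// Widths (3,529,688 parameters, recorded in pointnet_layout() on the R side):
//   input T-net:   per-point 5-64-128-256, pool, FC 256-128-64-25
//   encoder 1:     5-64-64
//   feature T-net: per-point 64-64-128-256, pool, FC 256-128-64-4096
//   encoder 2:     64-128-1024, max-pool
//   head:          1024-2300-256-3
#include "nn_core.h"

using namespace arma;
using ng::Mlp;
using ng::Example;

namespace {

struct PnNet {
  Mlp t1pp, t1fc, mlp1, t2pp, t2fc, mlp2, head;
};

Mlp make_mlp(ng::Reader& r, std::vector<std::pair<uword, uword>> dims,
             bool linear_last) {
  Mlp m;
  for (size_t i = 0; i < dims.size(); ++i) {
    m.layers.push_back(r.linear(dims[i].first, dims[i].second));
    bool last = (i + 1 == dims.size());
    m.acts.push_back(last && linear_last ? ng::Act::Linear : ng::Act::ReLU);
  }
  return m;
}

PnNet unpack_pn(const vec& w) {
  ng::Reader r(w);
  PnNet n;
  n.t1pp = make_mlp(r, {{64, 5}, {128, 64}, {256, 128}}, false);
  n.t1fc = make_mlp(r, {{128, 256}, {64, 128}, {25, 64}}, true);
  n.mlp1 = make_mlp(r, {{64, 5}, {64, 64}}, false);
  n.t2pp = make_mlp(r, {{64, 64}, {128, 64}, {256, 128}}, false);
  n.t2fc = make_mlp(r, {{128, 256}, {64, 128}, {4096, 64}}, true);
  n.mlp2 = make_mlp(r, {{128, 64}, {1024, 128}}, false);
  n.head = make_mlp(r, {{2300, 1024}, {256, 2300}, {3, 256}}, true);
  r.done();
  return n;
}

struct PnGrad {
  ng::MlpGrad t1pp, t1fc, mlp1, t2pp, t2fc, mlp2, head;
  void write(ng::Writer& w) {
    t1pp.write(w); t1fc.write(w); mlp1.write(w); t2pp.write(w);
    t2fc.write(w); mlp2.write(w); head.write(w);
  }
};

struct PnCache {
  Mlp::Cache c1, c2, c3, c4, c5, c6, c7;
  fmat X, Xt, F1, F2, F3, A1, A2;
  fmat T1, T2;
  uvec arg1, arg2, arg3;
};

fvec maxpool(const fmat& F, uvec& arg) {
  uword R = F.n_rows;
  fvec out(R);
  arg.set_size(R);
  for (uword i = 0; i < R; ++i) {
    uword a;
    out[i] = F.row(i).max(a);
    arg[i] = a;
  }
  return out;
}

fmat unpool(const fvec& dg, const uvec& arg, uword P) {
  fmat out(dg.n_elem, P, fill::zeros);
  for (uword i = 0; i < dg.n_elem; ++i) out(i, arg[i]) = dg[i];
  return out;
}

// X: 5 x P mirrored point features
fvec pn_forward_one(const PnNet& net, const fmat& X, PnCache& c) {
  c.X = X;
  uword P = X.n_cols;
  c.A1 = net.t1pp.forward(X, c.c1);
  fvec g1 = maxpool(c.A1, c.arg1);
  fmat t1o = net.t1fc.forward(fmat(g1), c.c2);
  c.T1 = reshape(t1o, 5, 5);
  c.Xt = c.T1 * X;
  c.F1 = net.mlp1.forward(c.Xt, c.c3);
  c.A2 = net.t2pp.forward(c.F1, c.c4);
  fvec g2 = maxpool(c.A2, c.arg2);
  fmat t2o = net.t2fc.forward(fmat(g2), c.c5);
  c.T2 = reshape(t2o, 64, 64);
  c.F2 = c.T2 * c.F1;
  c.F3 = net.mlp2.forward(c.F2, c.c6);
  fvec g3 = maxpool(c.F3, c.arg3);
  fmat out = net.head.forward(fmat(g3), c.c7);
  (void)P;
  return out.col(0);
}

void pn_backward_one(const PnNet& net, const PnCache& c, const fvec& dtheta,
                     PnGrad& G) {
  uword P = c.X.n_cols;
  fmat dg3 = net.head.backward(fmat(dtheta), c.c7, G.head.gW, G.head.gb);
  fmat dF3 = unpool(dg3.col(0), c.arg3, P);
  fmat dF2 = net.mlp2.backward(dF3, c.c6, G.mlp2.gW, G.mlp2.gb);
  fmat dT2 = dF2 * c.F1.t();
  fmat dF1 = c.T2.t() * dF2;
  fmat dg2 = net.t2fc.backward(reshape(dT2, 4096, 1), c.c5, G.t2fc.gW, G.t2fc.gb);
  fmat dA2 = unpool(dg2.col(0), c.arg2, P);
  dF1 += net.t2pp.backward(dA2, c.c4, G.t2pp.gW, G.t2pp.gb);
  fmat dXt = net.mlp1.backward(dF1, c.c3, G.mlp1.gW, G.mlp1.gb);
  fmat dT1 = dXt * c.X.t();
  fmat dg1 = net.t1fc.backward(reshape(dT1, 25, 1), c.c2, G.t1fc.gW, G.t1fc.gb);
  fmat dA1 = unpool(dg1.col(0), c.arg1, P);
  net.t1pp.backward(dA1, c.c1, G.t1pp.gW, G.t1pp.gb);
}

// normalise, drop b0s, mirror, stack features
fmat points_from_observed(const Example& ex) {
  mat qd; vec bd, ed;
  ng::normalise_split(ex, ex.s, qd, bd, ed);
  uword N = bd.n_elem;
  fmat X(5, 2 * N);
  for (uword i = 0; i < N; ++i) {
    for (int d = 0; d < 3; ++d) {
      X(d, i) = (float)qd(d, i);
      X(d, N + i) = (float)(-qd(d, i));
    }
    X(3, i) = X(3, N + i) = (float)ed[i];
    X(4, i) = X(4, N + i) = (float)bd[i];
  }
  return X;
}

fmat points_from_signals(const Example& ex, const vec& sig) {
  Example tmp = ex;
  tmp.s = sig;
  return points_from_observed(tmp);
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_pn_predict(const arma::vec& w, Rcpp::List voxels) {
  PnNet net = unpack_pn(w);
  uword n = voxels.size();
  mat theta(n, 3);
  for (uword i = 0; i < n; ++i) {
    Example ex = ng::example_from_list(voxels[i]);
    PnCache c;
    fvec th = pn_forward_one(net, points_from_observed(ex), c);
    theta.row(i) = conv_to<rowvec>::from(th.t());
  }
  return theta;
}

// [[Rcpp::export]]
Rcpp::List cpp_pn_loss_grad(const arma::vec& w, Rcpp::List voxel,
                            const arma::vec& target) {
  PnNet net = unpack_pn(w);
  Example ex = ng::example_from_list(voxel);
  PnCache c;
  fvec th = pn_forward_one(net, points_from_observed(ex), c);
  fvec resid = th - conv_to<fvec>::from(target);
  double loss = arma::accu(arma::square(conv_to<vec>::from(resid))) / 3.0;
  PnGrad G;
  pn_backward_one(net, c, resid * (2.0f / 3.0f), G);
  vec grad(w.n_elem, fill::zeros);
  ng::Writer wr(grad);
  G.write(wr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss, Rcpp::Named("grad") = grad);
}

// Identical training loop to the GNN's (grouped accumulation, per-batch SNR,
// dropout per presentation, Adam + clipping).
// [[Rcpp::export]]
Rcpp::List cpp_pn_epoch(const arma::vec& w_in, const arma::vec& m_in,
                        const arma::vec& v_in, int t_in,
                        Rcpp::List examples, Rcpp::List groups,
                        Rcpp::List conf) {
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
    PnNet net = unpack_pn(w);
    PnGrad G;
    float scale = 2.0f / (3.0f * B * P);
    for (uword p = 0; p < P; ++p) {
      double snr = snr_lo + (snr_hi - snr_lo) * unif_rand();
      for (uword r = 0; r < B; ++r) {
        const Example& ex0 = exs[gm(r, p) - 1];
        Example ex = ng::apply_dropout(ex0, drop_p, drop_lo, drop_hi);
        vec sig = ng::rician(ex.s, snr);
        PnCache c;
        fvec th = pn_forward_one(net, points_from_signals(ex, sig), c);
        fvec resid = th - conv_to<fvec>::from(ex0.theta);
        loss_sum += arma::accu(arma::square(conv_to<vec>::from(resid))) / 3.0;
        ++n_seen;
        pn_backward_one(net, c, resid * scale, G);
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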