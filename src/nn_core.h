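// Shared single-precision neural-network machinery: generic MLPs with
// manual backprop, Adam, Rician noise, and q-space graph construction.
// The network core runs in float32; graph geometry and the optimiser
// state are kept in double.
#ifndef NODDIGRAPH_NN_CORE_H
#define NODDIGRAPH_NN_CORE_H

#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <cstdint>

namespace ng {

using arma::fmat;
using arma::fvec;
using arma::mat;
using arma::vec;
using arma::uvec;
using arma::uword;

enum class Act { Linear, SiLU, ReLU };

inline fmat act_fwd(const fmat& z, Act a) {
  switch (a) {
    case Act::SiLU: return z % (1.0f / (1.0f + arma::exp(-z)));
    case Act::ReLU: return arma::clamp(z, 0.0f, arma::datum::inf);
    default:        return z;
  }
}

// derivative of activation wrt pre-activation z
inline fmat act_deriv(const fmat& z, Act a) {
  switch (a) {
    case Act::SiLU: {
      fmat s = 1.0f / (1.0f + arma::exp(-z));
      return s % (1.0f + z % (1.0f - s));
    }
    case Act::ReLU: return arma::conv_to<fmat>::from(z > 0.0f);
    default:        return arma::ones<fmat>(arma::size(z));
  }
}

struct Linear {
  fmat W;  // out x in
  fvec b;  // out
};

// Reads weight blocks sequentially from a flat double vector
// (column-major W then b per layer; layout mirrored in R).
struct Reader {
  const double* p;
  uword off = 0, n;
  Reader(const vec& w) : p(w.memptr()), n(w.n_elem) {}
  Linear linear(uword out, uword in) {
    Linear L;
    L.W.set_size(out, in);
    for (uword i = 0; i < out * in; ++i) L.W.memptr()[i] = (float)p[off + i];
    off += out * in;
    L.b.set_size(out);
    for (uword i = 0; i < out; ++i) L.b[i] = (float)p[off + i];
    off += out;
    return L;
  }
  void done() const {
    if (off != n) Rcpp::stop("weight vector length mismatch: used %d of %d", (int)off, (int)n);
  }
};

// Accumulates gradient blocks into a flat double vector in the same order.
struct Writer {
  vec& g;
  uword off = 0;
  Writer(vec& grad) : g(grad) {}
  void linear(const fmat& dW, const fvec& db) {
    double* p = g.memptr();
    for (uword i = 0; i < dW.n_elem; ++i) p[off + i] += (double)dW.memptr()[i];
    off += dW.n_elem;
    for (uword i = 0; i < db.n_elem; ++i) p[off + i] += (double)db[i];
    off += db.n_elem;
  }
};

// Multi-layer perceptron with per-layer activations and cached
// intermediates for backprop.
struct Mlp {
  std::vector<Linear> layers;
  std::vector<Act> acts;

  struct Cache {
    fmat input;
    std::vector<fmat> z;  // pre-activations
    std::vector<fmat> a;  // post-activations
  };

  fmat forward(const fmat& X, Cache& c) const {
    c.input = X;
    c.z.resize(layers.size());
    c.a.resize(layers.size());
    fmat h = X;
    for (size_t l = 0; l < layers.size(); ++l) {
      c.z[l] = layers[l].W * h;
      c.z[l].each_col() += layers[l].b;
      c.a[l] = act_fwd(c.z[l], acts[l]);
      h = c.a[l];
    }
    return h;
  }

  // returns gradient wrt input; appends parameter grads to `gw`/`gb`
  fmat backward(const fmat& dOut, const Cache& c,
                std::vector<fmat>& gW, std::vector<fvec>& gb) const {
    size_t L = layers.size();
    if (gW.size() != L) { gW.resize(L); gb.resize(L); }
    fmat d = dOut;
    for (size_t l = L; l-- > 0;) {
      fmat dz = d % act_deriv(c.z[l], acts[l]);
      const fmat& in = (l == 0) ? c.input : c.a[l - 1];
      fmat dW = dz * in.t();
      fvec db = arma::sum(dz, 1);
      if (gW[l].is_empty()) { gW[l] = dW; gb[l] = db; }
      else { gW[l] += dW; gb[l] += db; }
      d = layers[l].W.t() * dz;
    }
    return d;
  }
};

// Per-MLP gradient store (accumulated across examples of a batch group).
struct MlpGrad {
  std::vector<fmat> gW;
  std::vector<fvec> gb;
  void write(Writer& w) {
    for (size_t l = 0; l < gW.size(); ++l) w.linear(gW[l], gb[l]);
  }
};

// ---------------------------------------------------------------------------
// Adam with global-norm gradient clipping (double precision state)
// ---------------------------------------------------------------------------
struct Adam {
  vec m, v;
  double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t = 0;
  void step(vec& w, vec& grad, double lr, double clip) {
    double nrm = arma::norm(grad, 2);
    if (clip > 0 && nrm > clip) grad *= clip / nrm;
    ++t;
    m = beta1 * m + (1 - beta1) * grad;
    v = beta2 * v + (1 - beta2) * arma::square(grad);
    double c1 = 1 - std::pow(beta1, (double)t);
    double c2 = 1 - std::pow(beta2, (double)t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

// ---------------------------------------------------------------------------
// Graph construction (double precision geometry)
// ---------------------------------------------------------------------------
struct QGraphC {
  mat pos;      // 3 x M mirrored q positions (canonically ordered)
  vec bnode;    // M
  vec enode;    // M normalised signals
  uvec dst;     // E directed edges: message from src -> aggregated at dst
  uvec src;
  mat nfeat;    // 2 x M node features (E_i, b_i)
  mat efeat;    // 3 x E edge features (dist, |cos|, b_i - b_j)
};

// Build the mirrored k-NN graph from DWI-only measurements.
// q: 3 x N (non-zero b only), b: N, e: N normalised signals.
inline QGraphC build_qgraph(const mat& q, const vec& b, const vec& e, int k) {
  uword N = q.n_cols;
  if (N < 1) Rcpp::stop("graph needs at least one diffusion-weighted measurement");
  uword M = 2 * N;
  mat pos(3, M);
  vec bn(M), en(M);
  pos.cols(0, N - 1) = q;
  pos.cols(N, M - 1) = -q;
  bn.subvec(0, N - 1) = b;  bn.subvec(N, M - 1) = b;
  en.subvec(0, N - 1) = e;  en.subvec(N, M - 1) = e;

  // canonical node order: (b, x, y, z) ascending -> permutation invariance
  std::vector<uword> ord(M);
  for (uword i = 0; i < M; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](uword i, uword j) {
    if (bn[i] != bn[j]) return bn[i] < bn[j];
    if (pos(0, i) != pos(0, j)) return pos(0, i) < pos(0, j);
    if (pos(1, i) != pos(1, j)) return pos(1, i) < pos(1, j);
    return pos(2, i) < pos(2, j);
  });
  QGraphC g;
  g.pos.set_size(3, M); g.bnode.set_size(M); g.enode.set_size(M);
  for (uword i = 0; i < M; ++i) {
    g.pos.col(i) = pos.col(ord[i]);
    g.bnode[i] = bn[ord[i]];
    g.enode[i] = en[ord[i]];
  }

  int kk = std::min<int>(k, (int)M - 1);
  if (kk < 1) Rcpp::stop("graph needs at least two nodes");

  // brute-force k-NN with (distance, index) tie-break, symmetrised by union
  std::vector<std::vector<char>> adj(M, std::vector<char>(M, 0));
  std::vector<std::pair<double, uword>> cand(M - 1);
  for (uword i = 0; i < M; ++i) {
    uword c = 0;
    for (uword j = 0; j < M; ++j) {
      if (j == i) continue;
      double dx = g.pos(0, i) - g.pos(0, j);
      double dy = g.pos(1, i) - g.pos(1, j);
      double dz = g.pos(2, i) - g.pos(2, j);
      cand[c++] = {dx * dx + dy * dy + dz * dz, j};
    }
    std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
    for (int t = 0; t < kk; ++t) {
      uword j = cand[t].second;
      adj[i][j] = 1;  // j in N(i)
      adj[j][i] = 1;  // union symmetrisation
    }
  }
  std::vector<uword> dst, srcv;
  for (uword i = 0; i < M; ++i)
    for (uword j = 0; j < M; ++j)
      if (adj[i][j]) { dst.push_back(i); srcv.push_back(j); }
  uword E = dst.size();
  g.dst = uvec(dst); g.src = uvec(srcv);

  g.nfeat.set_size(2, M);
  for (uword i = 0; i < M; ++i) {
    g.nfeat(0, i) = g.enode[i];
    g.nfeat(1, i) = g.bnode[i];
  }
  g.efeat.set_size(3, E);
  for (uword eidx = 0; eidx < E; ++eidx) {
    uword i = g.dst[eidx], j = g.src[eidx];
    vec qi = g.pos.col(i), qj = g.pos.col(j);
    double ni = arma::norm(qi), nj = arma::norm(qj);
    g.efeat(0, eidx) = arma::norm(qi - qj);
    g.efeat(1, eidx) = std::abs(arma::dot(qi, qj) / (ni * nj));
    g.efeat(2, eidx) = g.bnode[i] - g.bnode[j];
  }
  return g;
}

// ---------------------------------------------------------------------------
// Voxel preprocessing shared by the trainers and predictors
// ---------------------------------------------------------------------------
struct Example {
  mat q;       // 3 x N (all measurements)
  vec b;       // N
  vec s;       // N signals (noise-free for training; observed for predict)
  uvec isb0;   // N 0/1
  vec theta;   // 3 targets (training only)
};

inline Example example_from_list(const Rcpp::List& ex) {
  Example E;
  Rcpp::NumericMatrix q = ex["q"];
  if (q.nrow() != 3) Rcpp::stop("q must be 3 x N");
  E.q = mat(q.begin(), 3, q.ncol());
  E.b = Rcpp::as<vec>(ex["b"]);
  E.s = Rcpp::as<vec>(ex["s"]);
  E.isb0 = arma::conv_to<uvec>::from(Rcpp::as<vec>(ex["isb0"]));
  if (ex.containsElementNamed("theta")) E.theta = Rcpp::as<vec>(ex["theta"]);
  return E;
}

// Rician noise via R's RNG (sigma relative to unit b0 level)
inline vec rician(const vec& s, double snr) {
  if (!std::isfinite(snr)) return s;
  double sigma = 1.0 / snr;
  vec out(s.n_elem);
  for (uword i = 0; i < s.n_elem; ++i) {
    double e1 = norm_rand() * sigma, e2 = norm_rand() * sigma;
    double a = s[i] + e1;
    out[i] = std::sqrt(a * a + e2 * e2);
  }
  return out;
}

// Normalise by mean b0 and keep DWIs; returns DWI-only (q, b, E)
inline void normalise_split(const Example& ex, const vec& signals,
                            mat& qd, vec& bd, vec& ed) {
  double b0sum = 0; uword nb0 = 0;
  for (uword i = 0; i < ex.b.n_elem; ++i)
    if (ex.isb0[i]) { b0sum += signals[i]; ++nb0; }
  if (nb0 == 0) Rcpp::stop("no b=0 measurement; cannot normalise");
  double b0mean = b0sum / nb0;
  if (b0mean <= 0) Rcpp::stop("non-positive mean b0 signal");
  uword nd = ex.b.n_elem - nb0;
  qd.set_size(3, nd); bd.set_size(nd); ed.set_size(nd);
  uword c = 0;
  for (uword i = 0; i < ex.b.n_elem; ++i) {
    if (ex.isb0[i]) continue;
    qd.col(c) = ex.q.col(i);
    bd[c] = ex.b[i];
    ed[c] = signals[i] / b0mean;
    ++c;
  }
}

// Measurement dropout: with probability p, drop floor(f * Ndwi) random DWIs,
// f ~ U(lo, hi); b0s always retained, at least one DWI kept.
inline Example apply_dropout(const Example& ex, double p, double lo, double hi) {
  if (unif_rand() >= p) return ex;
  double f = lo + (hi - lo) * unif_rand();
  std::vector<uword> dwi;
  for (uword i = 0; i < ex.b.n_elem; ++i) if (!ex.isb0[i]) dwi.push_back(i);
  uword ndrop = (uword)std::floor(f * (double)dwi.size());
  if (ndrop >= dwi.size()) ndrop = dwi.size() - 1;
  if (ndrop == 0) return ex;
  // partial Fisher-Yates using R's RNG
  for (uword t = 0; t < ndrop; ++t) {
    uword r = t + (uword)(unif_rand() * (double)(dwi.size() - t));
    if (r >= dwi.size()) r = dwi.size() - 1;
    std::swap(dwi[t], dwi[r]);
  }
  std::vector<char> drop(ex.b.n_elem, 0);
  for (uword t = 0; t < ndrop; ++t) drop[dwi[t]] = 1;
  Example out;
  uword keep = ex.b.n_elem - ndrop;
  out.q.set_size(3, keep); out.b.set_size(keep); out.s.set_size(keep);
  out.isb0.set_size(keep);
  uword c = 0;
  for (uword i = 0; i < ex.b.n_elem; ++i) {
    if (drop[i]) continue;
    out.q.col(c) = ex.q.col(i);
    out.b[c] = ex.b[i];
    out.s[c] = ex.s[i];
    out.isb0[c] = ex.isb0[i];
    ++c;
  }
  out.theta = ex.theta;
  return out;
}

}  // namespace ng

#endif
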