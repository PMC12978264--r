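// NODDI forward-model kernels. The Watson-dispersed stick (intra-neurite)
// compartment is evaluated by fixed-order product quadrature on the sphere
// (Gauss-Legendre in cos(theta) on [0,1] x midpoint rule in phi on [0,pi],
// exploiting the antipodal and azimuthal symmetries of the integrand).
// The zeppelin (extra-neurite) and free-water compartments are closed form.
#include "nn_core.h"

using namespace arma;

// Watson-averaged stick signal for one voxel across measurements.
// a[m] = b_m * d_par, cpsi[m] = |g_m . mu|. Quadrature nodes/weights for
// t = cos(theta) on [0,1] are supplied by the caller (package-level cache).
// [[Rcpp::export]]
arma::vec cpp_intra_signal(const arma::vec& a, const arma::vec& cpsi,
                           double kappa, const arma::vec& tnodes,
                           const arma::vec& tweights, int nphi) {
  uword nt = tnodes.n_elem, N = a.n_elem;
  // beyond the resolvable concentration range the Watson density is a
  // delta at mu for any practical purpose: use the stick limit
  if (kappa > 2e4) {
    vec out(N);
    for (uword m = 0; m < N; ++m) out[m] = std::exp(-a[m] * cpsi[m] * cpsi[m]);
    return out;
  }
  vec wt(nt), t2(nt), st(nt);
  double denom = 0;
  for (uword i = 0; i < nt; ++i) {
    double t = tnodes[i];
    t2[i] = t * t;
    st[i] = std::sqrt(std::max(0.0, 1.0 - t2[i]));
    wt[i] = tweights[i] * std::exp(kappa * (t2[i] - 1.0));  // e^{-kappa} folded in
    denom += wt[i];
  }
  vec cphi(nphi);
  for (int j = 0; j < nphi; ++j)
    cphi[j] = std::cos((j + 0.5) * M_PI / nphi);
  vec out(N);
  for (uword m = 0; m < N; ++m) {
    double c = cpsi[m], s = std::sqrt(std::max(0.0, 1.0 - c * c));
    double acc = 0;
    for (uword i = 0; i < nt; ++i) {
      double ct = c * tnodes[i], sst = s * st[i];
      double sum = 0;
      for (int j = 0; j < nphi; ++j) {
        double d = ct + sst * cphi[j];
        sum += std::exp(-a[m] * d * d);
      }
      acc += wt[i] * sum / nphi;
    }
    out[m] = acc / denom;
  }
  return out;
}

// Noise-free NODDI signals for many voxels under one protocol.
// b: N, g: 3 x N (unit where b > 0), params: n x 3 (ndi, odi unused, fwf),
// kappa/tau1: n (precomputed from odi), mu: 3 x n.
// [[Rcpp::export]]
arma::mat cpp_simulate_many(const arma::vec& b, const arma::mat& g,
                            const arma::mat& params, const arma::vec& kappa,
                            const arma::vec& tau1, const arma::mat& mu,
                            double d_par, double d_iso,
                            const arma::vec& tnodes, const arma::vec& tweights,
                            int nphi) {
  uword N = b.n_elem, n = params.n_rows;
  if (g.n_cols != N || g.n_rows != 3) Rcpp::stop("g must be 3 x length(b)");
  mat out(n, N);
  vec a = b * d_par;
  vec fw = arma::exp(-b * d_iso);
  for (uword v = 0; v < n; ++v) {
    double ndi = params(v, 0), fwf = params(v, 2);
    double t1 = tau1[v];
    double d_perp = d_par * (1.0 - ndi);
    vec cpsi(N);
    for (uword m = 0; m < N; ++m)
      cpsi[m] = std::abs(arma::dot(g.col(m), mu.col(v)));
    vec aic = cpp_intra_signal(a, cpsi, kappa[v], tnodes, tweights, nphi);
    for (uword m = 0; m < N; ++m) {
      if (b[m] <= 0) { out(v, m) = 1.0; continue; }
      double c2 = cpsi[m] * cpsi[m];
      double proj = t1 * c2 + 0.5 * (1.0 - t1) * (1.0 - c2);
      double gDg = d_perp + (d_par - d_perp) * proj;
      double aec = std::exp(-b[m] * gDg);
      out(v, m) = (1.0 - fwf) * (ndi * aic[m] + (1.0 - ndi) * aec) + fwf * fw[m];
    }
  }
  return out;
}
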