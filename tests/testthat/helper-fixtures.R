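# Shared fixtures: all synthetic, generated in code.

# small two-shell protocol for fast tests
tiny_protocol <- function(n_per_shell = 15, n_b0 = 2, seed = 501) {
  make_shell_protocol(c(1, 2.5), rep(n_per_shell, 2), n_b0 = n_b0,
                      label = "tiny", seed = seed)
}

default_params <- function(mu = c(1, 1, 1)) {
  microstructure_params(0.5, 0.4, 0.2, mu)
}

# independent dense-quadrature oracle for the Watson-stick integral,
# written against the raw 2D integral (reduced frame), pure R
dense_intra_oracle <- function(a, cpsi, kappa, nt = 200, nphi = 200) {
  gl <- pracma::gaussLegendre(nt, 0, 1)
  phi <- (seq_len(nphi) - 0.5) * pi / nphi
  s <- sqrt(max(0, 1 - cpsi^2))
  w <- gl$w * exp(kappa * (gl$x^2 - 1))
  num <- 0
  for (i in seq_len(nt)) {
    d <- cpsi * gl$x[i] + s * sqrt(1 - gl$x[i]^2) * cos(phi)
    num <- num + w[i] * mean(exp(-a * d^2))
  }
  num / sum(w)
}

# brute-force surface integral of f(n) * Watson(n; mu, kappa) over S^2,
# on a fine lat-long grid (independent of the package quadrature frame)
sphere_watson_average <- function(f, mu, kappa, nth = 400, nph = 400) {
  th <- (seq_len(nth) - 0.5) * pi / nth
  ph <- (seq_len(nph) - 0.5) * 2 * pi / nph
  acc_num <- 0
  acc_den <- 0
  for (i in seq_len(nth)) {
    st <- sin(th[i]); ct <- cos(th[i])
    n <- cbind(st * cos(ph), st * sin(ph), ct)
    w <- exp(kappa * ((n %*% mu)^2 - 1)) * st
    acc_num <- acc_num + sum(w * f(n))
    acc_den <- acc_den + sum(w)
  }
  acc_num / acc_den
}

rotate_protocol <- function(proto, Q) {
  protocol(proto$b, proto$g %*% t(Q), label = proto$label)
}

permute_voxel <- function(voxel, perm) {
  p <- voxel$protocol
  voxel_data(protocol(p$b[perm], p$g[perm, , drop = FALSE], p$label),
             voxel$signals[perm])
}

# quick low-cost trained weights for invariance checks on trained models
quick_trained_gnn <- function() {
  cfg <- training_config(n_voxels = 10, protocols_per_voxel = 2, epochs = 2,
                         batch_size = 5, seed = 77)
  ds <- build_training_set(cfg)
  train_gnn(gnn_init(5), ds, cfg)
}
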