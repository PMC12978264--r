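# Forward model: Watson machinery, compartment signals, noise

test_that("odi/kappa reparameterisation behaves and round-trips", {
  expect_equal(odi_to_kappa(0.5), 1)
  expect_equal(odi_to_kappa(0.25), 1 / tan(pi / 8), tolerance = 1e-12)
  expect_equal(odi_to_kappa(0.25), 2.41421, tolerance = 1e-5)
  # strictly decreasing, diverging towards odi -> 0
  odis <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(odi_to_kappa(odis)) < 0))
  expect_gt(odi_to_kappa(1e-6), 1e5)
  expect_equal(kappa_to_odi(odi_to_kappa(odis)), odis, tolerance = 1e-12)
  expect_error(odi_to_kappa(0), "odi")
  expect_error(odi_to_kappa(1), "odi")
})

test_that("watson_tau1 matches limits and brute-force spherical integration", {
  expect_equal(watson_tau1(0), 1 / 3)
  expect_lt(abs(watson_tau1(1e8) - 1), 1e-6)
  expect_error(watson_tau1(-1), "non-negative")
  # independent oracle: integrate (mu.n)^2 against the Watson density
  mu <- c(0, 0, 1)
  for (kap in c(0.1, 1, 9, 25)) {
    oracle <- sphere_watson_average(function(n) n[, 3]^2, mu, kap)
    expect_equal(watson_tau1(kap), oracle, tolerance = 1e-5)
  }
  expect_equal(watson_tau1(1), 0.42923, tolerance = 1e-4)
  # series branch continuous at the switch point
  expect_equal(watson_tau1(9.9e-7), watson_tau1(1.1e-6), tolerance = 1e-7)
})

test_that("intra-neurite signal matches closed forms and the dense oracle", {
  mu <- c(0, 0, 1)
  expect_equal(intra_signal(0, c(1, 0, 0), mu, 2), 1)
  # isotropic sticks: (sqrt(pi)/2) erf(sqrt(b d)) / sqrt(b d)
  bd <- 1.7
  closed <- sqrt(pi) / 2 * pracma::erf(sqrt(bd)) / sqrt(bd)
  expect_equal(intra_signal(1, c(1, 0, 0), mu, 0), closed, tolerance = 1e-6)
  expect_equal(closed, 0.6354, tolerance = 1e-4)
  # concentrated limit: stick along mu
  expect_equal(intra_signal(1, mu, mu, 1e7), exp(-1.7), tolerance = 1e-4)
  g <- c(sqrt(0.5), 0, sqrt(0.5))
  expect_equal(intra_signal(2, g, mu, 1e7), exp(-2 * 1.7 * 0.5), tolerance = 1e-3)
  # dense-oracle agreement across the working range
  for (b in c(0.25, 2.5, 5)) {
    for (odi in c(0.025, 0.3, 0.975)) {
      for (cp in c(0, 0.6, 1)) {
        kap <- odi_to_kappa(odi)
        v <- intra_signal(b, c(sqrt(1 - cp^2), 0, cp), mu, kap)
        expect_equal(v, dense_intra_oracle(b * 1.7, cp, kap), tolerance = 1e-6)
      }
    }
  }
})

test_that("extra-neurite zeppelin matches its closed-form limits", {
  mu <- c(0, 0, 1)
  expect_equal(extra_signal(0, c(1, 0, 0), mu, 2, 0.5), 1)
  # isotropic dispersion: direction-independent mean diffusivity
  for (gdir in list(c(1, 0, 0), c(0, 0, 1), c(1, 1, 1) / sqrt(3))) {
    expect_equal(extra_signal(2, gdir, mu, 0, 0.4),
                 exp(-2 * 1.7 * (1 - 2 * 0.4 / 3)), tolerance = 1e-12)
  }
  # no dispersion, perpendicular gradient: pure radial diffusivity
  expect_equal(extra_signal(1.5, c(1, 0, 0), mu, 1e9, 0.3),
               exp(-1.5 * 1.7 * (1 - 0.3)), tolerance = 1e-6)
  # quadrature cross-check: zeppelin equals Watson average of gT(nnT)g scaled
  kap <- odi_to_kappa(0.4)
  gdir <- c(0.6, 0, 0.8)
  oracle_proj <- sphere_watson_average(function(n) (n %*% gdir)^2, mu, kap)
  d_perp <- 1.7 * (1 - 0.35)
  expect_equal(extra_signal(2, gdir, mu, kap, 0.35),
               exp(-2 * (d_perp + (1.7 - d_perp) * oracle_proj)),
               tolerance = 1e-5)
})

test_that("composite signal: b0 level, free-water limit, monotone b-decay", {
  pars <- default_params()
  expect_equal(noddi_signal(0, c(0, 0, 1), pars), 1)
  pf <- microstructure_params(0.5, 0.5, 1 - 1e-9)
  expect_equal(noddi_signal(1, c(0, 0, 1), pf), exp(-3.0), tolerance = 1e-6)
  expect_equal(exp(-3.0), 0.049787, tolerance = 1e-5)
  bs <- seq(0, 5, by = 0.25)
  for (gdir in list(c(0, 0, 1), c(1, 0, 0))) {
    e <- noddi_signal(bs, matrix(rep(gdir, length(bs)), ncol = 3, byrow = TRUE), pars)
    expect_true(all(diff(e) < 0))
  }
})

test_that("signal is rotation-equivariant and antipodally symmetric", {
  pars <- default_params(mu = c(0.3, -0.5, 0.8))
  set.seed(11)
  g <- sample_sphere_directions(10)
  b <- runif(10, 0.25, 5)
  e0 <- noddi_signal(b, g, pars)
  # antipodal: exact by construction
  expect_identical(noddi_signal(b, -g, pars), e0)
  # joint rotation of (g, mu)
  for (Q in random_rotations(3)) {
    pr <- microstructure_params(pars$ndi, pars$odi, pars$fwf,
                                as.numeric(Q %*% pars$mu))
    expect_equal(noddi_signal(b, g %*% t(Q), pr), e0, tolerance = 1e-6)
  }
  # mu and -mu identical
  pm <- microstructure_params(pars$ndi, pars$odi, pars$fwf, -pars$mu)
  expect_equal(noddi_signal(b, g, pm), e0, tolerance = 1e-12)
})

test_that("Rician noise has the right law and respects the SNR", {
  x <- runif(20)
  expect_identical(add_rician_noise(x, Inf), x)
  expect_error(add_rician_noise(x, 0), "positive")
  expect_error(add_rician_noise(x, -3), "positive")
  # Rayleigh mean at S = 0, sigma = 1
  set.seed(201)
  draws <- add_rician_noise(rep(0, 1e6), 1)
  se <- sqrt((2 - pi / 2) / 1e6)
  expect_lt(abs(mean(draws) - sqrt(pi / 2)), 3 * se)
  # high SNR: essentially a no-op
  set.seed(202)
  y <- add_rician_noise(rep(1, 1e5), 1000)
  expect_gte(mean(abs(y - 1) < 0.01), 0.999)
  expect_true(all(y > 0))
})

test_that("voxel simulation is deterministic and protocol-aligned", {
  proto <- tiny_protocol()
  pars <- default_params()
  set.seed(7)
  v1 <- simulate_voxel(proto, pars, snr = 20)
  set.seed(7)
  v2 <- simulate_voxel(proto, pars, snr = 20)
  expect_identical(v1$signals, v2$signals)
  expect_length(v1$signals, proto$n)
  expect_true(all(v1$signals > 0))
  # all-b0 protocol, no noise -> all signals exactly 1
  p0 <- protocol(rep(0, 4), matrix(0, 4, 3))
  pars0 <- default_params()
  expect_equal(simulate_voxel(p0, pars0, snr = Inf)$signals, rep(1, 4))
  # noise-free b0s are 1 even in mixed protocols
  vnf <- simulate_voxel(proto, pars, snr = Inf)
  expect_equal(vnf$signals[proto$b0_indices], rep(1, length(proto$b0_indices)))
})

test_that("batch simulation agrees with the scalar path", {
  proto <- tiny_protocol()
  tab <- rbind(params_table(default_params(mu = c(1, 0, 0))),
               params_table(microstructure_params(0.8, 0.1, 0.05, c(0, 1, 2))))
  sig <- simulate_signals(proto, tab)
  expect_equal(dim(sig), c(2, proto$n))
  for (r in 1:2) {
    pars <- microstructure_params(tab$ndi[r], tab$odi[r], tab$fwf[r],
                                  c(tab$mu_x[r], tab$mu_y[r], tab$mu_z[r]))
    expect_equal(sig[r, ], noddi_signal(proto$b, proto$g, pars), tolerance = 1e-12)
  }
})
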