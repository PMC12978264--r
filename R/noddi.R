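#' Tissue diffusivity constants
#'
#' Fixed diffusivities of the NODDI forward model: the intrinsic axial
#' diffusivity of neurites (`d_par`) and the isotropic free-water
#' diffusivity (`d_iso`), both in um^2/ms. The standard NODDI values are
#' used as defaults; they are held fixed across all simulations.
#'
#' @param d_par axial diffusivity of the neurite compartment, um^2/ms
#' @param d_iso free-water diffusivity, um^2/ms
#' @return an object of class `tissue_constants`
#' @export
tissue_constants <- function(d_par = 1.7, d_iso = 3.0) {
  stopifnot(d_par > 0, d_iso > 0)
  structure(list(d_par = d_par, d_iso = d_iso), class = "tissue_constants")
}

#' Map orientation dispersion index to Watson concentration
#'
#' The NODDI reparameterisation kappa = 1 / tan(odi * pi / 2): ODI near 0
#' means tightly packed fibres (large kappa), ODI near 1 fully dispersed
#' (kappa near 0).
#'
#' @param odi orientation dispersion index in (0, 1)
#' @return Watson concentration kappa > 0
#' @export
odi_to_kappa <- function(odi) {
  if (any(odi <= 0 | odi >= 1)) stop("odi must lie strictly inside (0, 1)")
  1 / tan(odi * pi / 2)
}

#' @rdname odi_to_kappa
#' @param kappa Watson concentration parameter, >= 0
#' @export
kappa_to_odi <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be non-negative")
  (2 / pi) * atan(1 / kappa)
}

#' Watson-averaged squared cosine
#'
#' The mean of (mu . n)^2 under the Watson density W(n; mu, kappa) on the
#' sphere, i.e. the leading eigenvalue of the orientation-dispersion tensor
#' <n n^T>. Computed from the closed form
#' tau1 = 1 / (2 sqrt(kappa) D(sqrt(kappa))) - 1 / (2 kappa)
#' with D the Dawson function; a series branch is used near kappa = 0 and
#' an asymptotic Dawson expansion for very large kappa.
#'
#' @param kappa Watson concentration, >= 0 (vectorised)
#' @return tau1 in \[1/3, 1)
#' @export
watson_tau1 <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be non-negative (bipolar Watson not supported)")
  out <- numeric(length(kappa))
  small <- kappa < 1e-6
  out[small] <- 1 / 3 + 4 * kappa[small] / 45
  k <- kappa[!small]
  if (length(k)) {
    sk <- sqrt(k)
    daw <- numeric(length(k))
    big <- k > 625
    if (any(!big)) {
      x <- sk[!big]
      daw[!big] <- sqrt(pi) / 2 * exp(-x^2) * pracma::erfi(x)
    }
    if (any(big)) {
      x <- sk[big]
      daw[big] <- (1 / (2 * x)) * (1 + 1 / (2 * x^2) + 3 / (4 * x^4) + 15 / (8 * x^6))
    }
    out[!small] <- 1 / (2 * sk * daw) - 1 / (2 * k)
  }
  out
}

# Gauss-Legendre x midpoint quadrature used for the Watson-stick integral;
# the order was fixed once by validating against dense quadrature (see the
# methods vignette) and is cached per session.
ng_quadrature <- function() {
  if (is.null(.ng$quad)) {
    gl <- pracma::gaussLegendre(32, 0, 1)
    .ng$quad <- list(t = gl$x, w = gl$w, nphi = 32L)
  }
  .ng$quad
}

#' Intra-neurite compartment signal
#'
#' Signal of the Watson-dispersed stick compartment: the stick response
#' exp(-b d_par (g . n)^2) averaged over fibre orientations n drawn from a
#' Watson distribution with mean direction `mu` and concentration `kappa`.
#' Evaluated by fixed-order spherical product quadrature.
#'
#' @param b b-value(s), ms/um^2
#' @param g unit gradient direction(s): length-3 vector or N x 3 matrix
#' @param mu unit principal fibre direction
#' @param kappa Watson concentration, >= 0
#' @param constants [tissue_constants()]
#' @return signal attenuation(s) in (0, 1]
#' @export
intra_signal <- function(b, g, mu, kappa, constants = tissue_constants()) {
  if (any(b < 0)) stop("b-values must be non-negative")
  if (kappa < 0) stop("kappa must be non-negative")
  g <- rbind(g)
  mu <- mu / sqrt(sum(mu^2))
  cpsi <- pmin(abs(as.vector(g %*% mu)), 1)
  q <- ng_quadrature()
  as.vector(cpp_intra_signal(b * constants$d_par, cpsi, kappa, q$t, q$w, q$nphi))
}

#' Extra-neurite compartment signal
#'
#' Zeppelin compartment with tortuosity coupling: a Gaussian anisotropic
#' tensor whose radial diffusivity is d_par * (1 - ndi) and whose
#' orientation average follows the same Watson distribution as the sticks,
#' D = d_perp I + (d_par - d_perp) <n n^T> with
#' <n n^T> = tau1 mu mu^T + (1 - tau1)/2 (I - mu mu^T).
#'
#' @inheritParams intra_signal
#' @param ndi neurite density index in (0, 1), sets the tortuosity
#' @return signal attenuation(s) in (0, 1]
#' @export
extra_signal <- function(b, g, mu, kappa, ndi, constants = tissue_constants()) {
  if (any(b < 0)) stop("b-values must be non-negative")
  if (kappa < 0) stop("kappa must be non-negative")
  if (ndi <= 0 || ndi >= 1) stop("ndi must lie strictly inside (0, 1)")
  g <- rbind(g)
  mu <- mu / sqrt(sum(mu^2))
  tau1 <- watson_tau1(kappa)
  d_par <- constants$d_par
  d_perp <- d_par * (1 - ndi)
  c2 <- pmin(as.vector(g %*% mu)^2, 1)
  proj <- tau1 * c2 + 0.5 * (1 - tau1) * (1 - c2)
  exp(-b * (d_perp + (d_par - d_perp) * proj))
}

#' Microstructure parameter set
#'
#' The scalar NODDI parameters plus the principal fibre direction. `mu` is
#' normalised to unit length; by the antipodal symmetry of the model, `mu`
#' and `-mu` describe the same voxel.
#'
#' @param ndi neurite density index, in (0, 1)
#' @param odi orientation dispersion index, in (0, 1)
#' @param fwf free-water fraction, in (0, 1)
#' @param mu principal fibre direction (any non-zero 3-vector; normalised)
#' @return an object of class `microstructure_params`
#' @export
microstructure_params <- function(ndi, odi, fwf, mu = c(0, 0, 1)) {
  for (v in c(ndi = ndi, odi = odi, fwf = fwf)) {
    if (v <= 0 || v >= 1) stop("ndi, odi and fwf must lie strictly inside (0, 1)")
  }
  nrm <- sqrt(sum(mu^2))
  if (nrm < 1e-12) stop("mu must be a non-zero vector")
  structure(list(ndi = ndi, odi = odi, fwf = fwf, mu = mu / nrm),
            class = "microstructure_params")
}

#' Full NODDI signal
#'
#' Three-compartment composition: intra-neurite Watson-dispersed sticks,
#' tortuosity-coupled extra-neurite zeppelin, and isotropic free water,
#' E = (1 - fwf) (ndi A_ic + (1 - ndi) A_ec) + fwf exp(-b d_iso).
#' At b = 0 the normalised signal is exactly 1.
#'
#' @inheritParams intra_signal
#' @param params [microstructure_params()]
#' @return normalised signal(s) in (0, 1]
#' @export
noddi_signal <- function(b, g, params, constants = tissue_constants()) {
  stopifnot(inherits(params, "microstructure_params"))
  g <- rbind(g)
  kappa <- odi_to_kappa(params$odi)
  aic <- intra_signal(b, g, params$mu, kappa, constants)
  aec <- extra_signal(b, g, params$mu, kappa, params$ndi, constants)
  e <- (1 - params$fwf) * (params$ndi * aic + (1 - params$ndi) * aec) +
    params$fwf * exp(-b * constants$d_iso)
  e[b == 0] <- 1
  e
}

#' Add Rician noise
#'
#' Magnitude-MR noise: S -> sqrt((S + e1)^2 + e2^2) with e1, e2 iid
#' N(0, sigma^2) and sigma = 1/snr. The convention is that signals are
#' normalised so the noise-free b = 0 level is 1, making snr the b0
#' signal-to-noise ratio. `snr = Inf` returns the input unchanged.
#'
#' @param signals vector or matrix of non-negative signals
#' @param snr signal-to-noise ratio at the b0 level; positive or `Inf`
#' @return noised signals (all strictly positive almost surely)
#' @export
add_rician_noise <- function(signals, snr) {
  if (is.na(snr) || snr <= 0) stop("snr must be positive (or Inf for no noise)")
  if (!is.finite(snr)) return(signals)
  sigma <- 1 / snr
  e1 <- rnorm(length(signals), sd = sigma)
  e2 <- rnorm(length(signals), sd = sigma)
  out <- sqrt((signals + e1)^2 + e2^2)
  attributes(out) <- attributes(signals)
  out
}

#' Simulate one voxel
#'
#' Noise-free NODDI signals at every acquisition point of `protocol`
#' (exactly 1 at b = 0), followed by Rician noise at the given SNR.
#'
#' @param protocol a [protocol()]
#' @param params [microstructure_params()]
#' @param snr b0 signal-to-noise ratio (`Inf` for noise-free)
#' @param constants [tissue_constants()]
#' @return a `voxel_data` object: the protocol plus aligned signals
#' @export
simulate_voxel <- function(protocol, params, snr = Inf,
                           constants = tissue_constants()) {
  stopifnot(inherits(protocol, "protocol"), inherits(params, "microstructure_params"))
  sig <- simulate_signals(protocol, params_table(params), constants)[1, ]
  voxel_data(protocol, add_rician_noise(sig, snr))
}

#' Simulate many voxels under one protocol
#'
#' Vectorised noise-free forward simulation: one row of signals per
#' parameter set. Noise is not added here; see [add_rician_noise()].
#'
#' @param protocol a [protocol()]
#' @param params data frame with columns ndi, odi, fwf, mu_x, mu_y, mu_z
#'   (see [params_table()] / [sample_params()])
#' @param constants [tissue_constants()]
#' @return numeric matrix, `nrow(params)` x `protocol$n`
#' @export
simulate_signals <- function(protocol, params, constants = tissue_constants()) {
  stopifnot(inherits(protocol, "protocol"))
  pm <- as.matrix(params[, c("ndi", "odi", "fwf")])
  mu <- t(as.matrix(params[, c("mu_x", "mu_y", "mu_z")]))
  mu <- sweep(mu, 2, sqrt(colSums(mu^2)), "/")
  kappa <- odi_to_kappa(pm[, "odi"])
  tau1 <- watson_tau1(kappa)
  q <- ng_quadrature()
  cpp_simulate_many(protocol$b, t(protocol$g), pm, kappa, tau1, mu,
                    constants$d_par, constants$d_iso, q$t, q$w, q$nphi)
}

#' @rdname simulate_voxel
#' @param signals numeric vector of measured signals aligned with
#'   `protocol` points
#' @export
voxel_data <- function(protocol, signals) {
  stopifnot(inherits(protocol, "protocol"))
  if (length(signals) != protocol$n) {
    stop("signal count does not match protocol size")
  }
  if (any(signals <= 0)) stop("signals must be strictly positive")
  structure(list(protocol = protocol, signals = as.numeric(signals)),
            class = "voxel_data")
}

# one-row parameter table from a microstructure_params object
#' @rdname microstructure_params
#' @param params a `microstructure_params` object
#' @export
params_table <- function(params) {
  stopifnot(inherits(params, "microstructure_params"))
  data.frame(ndi = params$ndi, odi = params$odi, fwf = params$fwf,
             mu_x = params$mu[1], mu_y = params$mu[2], mu_z = params$mu[3])
}

# internal: voxel_data -> the flat structure consumed by the C++ core
as_cpp_voxel <- function(voxel, theta = NULL) {
  p <- voxel$protocol
  out <- list(q = t(p$q), b = p$b, s = voxel$signals,
              isb0 = as.numeric(p$b == 0))
  if (!is.null(theta)) out$theta <- as.numeric(theta)
  out
}
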