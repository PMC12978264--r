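#' Conventional NODDI fitting by nonlinear least squares
#'
#' Box-constrained least squares on the normalised signals: minimises
#' sum_i (E_i - E_hat_i(theta))^2 over (NDI, ODI, FWF) and the fibre
#' direction (parameterised by spherical angles), using
#' Levenberg-Marquardt with multiple deterministic starts. The fibre
#' direction is initialised from the principal eigenvector of the
#' attenuation-weighted rank-2 moment of the gradient directions, plus a
#' fixed grid of scalar starts; the best-residual solution is kept.
#' Starts stop early once a near-zero residual is found.
#'
#' @param voxel a [voxel_data()] with at least one b0 measurement
#' @param constants [tissue_constants()]
#' @param starts optional matrix of (ndi, odi, fwf) start rows; defaults
#'   to the 2 x 2 x 2 grid \{0.3, 0.7\} x \{0.2, 0.8\} x \{0.1, 0.5\}
#' @param ftol residual sum of squares below which remaining starts are
#'   skipped
#' @return an object of class `fit_result`: `theta_hat`
#'   ([microstructure_params()]), `residual` (sum of squared residuals),
#'   `converged`, `n_restarts_used`, and `non_identifiable` (TRUE when
#'   the free-water fraction saturates and NDI/ODI are meaningless)
#' @export
nlls_fit <- function(voxel, constants = tissue_constants(), starts = NULL,
                     ftol = 1e-12) {
  stopifnot(inherits(voxel, "voxel_data"))
  E <- normalise_signals(voxel)
  p <- voxel$protocol
  dwi <- p$b > 0
  b <- p$b[dwi]
  g <- p$g[dwi, , drop = FALSE]
  e_obs <- E[dwi]
  quad <- ng_quadrature()

  # fractions are optimised on the logit scale: unconstrained interior
  # optimisation avoids the flat-gradient sticking of projected bounds
  # (the dispersion axis is nearly flat near ODI -> 1)
  squash <- function(x) 1 / (1 + exp(-x))
  unsquash <- function(p) log(p / (1 - p))
  resid_fun <- function(par) {
    f <- squash(par[1:3])
    mu <- c(sin(par[4]) * cos(par[5]), sin(par[4]) * sin(par[5]), cos(par[4]))
    kappa <- odi_to_kappa(f[2])
    pred <- cpp_simulate_many(b, t(g), matrix(f, 1), kappa, watson_tau1(kappa),
                              matrix(mu, 3), constants$d_par, constants$d_iso,
                              quad$t, quad$w, quad$nphi)[1, ]
    pred - e_obs
  }

  # direction start: principal eigenvector of sum (1 - E_i) g_i g_i^T
  wts <- pmax(1 - e_obs, 0)
  Mten <- crossprod(g * sqrt(wts))
  mu0 <- eigen(Mten, symmetric = TRUE)$vectors[, 1]
  th0 <- acos(pmin(pmax(mu0[3], -1), 1))
  ph0 <- atan2(mu0[2], mu0[1])

  if (is.null(starts)) {
    starts <- as.matrix(expand.grid(ndi = c(0.3, 0.7), odi = c(0.2, 0.8),
                                    fwf = c(0.1, 0.5)))
  }

  run_start <- function(par0) {
    try(minpack.lm::nls.lm(
      par = par0, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  }
  best <- NULL
  used <- 0L
  for (s in seq_len(nrow(starts))) {
    used <- used + 1L
    fit <- run_start(c(unsquash(starts[s, ]), th0, ph0))
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance < ftol * length(e_obs)) break
  }
  # rescue pass for the nearly flat dispersion axis: restart from the best
  # scalars with a sweep of ODI values
  if (!is.null(best) && best$deviance > 1e-9 * length(e_obs)) {
    fb <- squash(best$par[1:3])
    for (odi0 in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
      used <- used + 1L
      fit <- run_start(c(unsquash(c(fb[1], odi0, fb[3])), best$par[4], best$par[5]))
      if (inherits(fit, "try-error")) next
      if (fit$deviance < best$deviance) best <- fit
      if (best$deviance < ftol * length(e_obs)) break
    }
  }
  if (is.null(best)) {
    return(structure(list(theta_hat = NULL, residual = Inf, converged = FALSE,
                          n_restarts_used = used, non_identifiable = NA),
                     class = "fit_result"))
  }
  par <- best$par
  f <- pmin(pmax(squash(par[1:3]), 1e-6), 1 - 1e-6)
  mu <- c(sin(par[4]) * cos(par[5]), sin(par[4]) * sin(par[5]), cos(par[4]))
  if (mu[3] < 0) mu <- -mu  # antipodal canonicalisation
  structure(list(
    theta_hat = microstructure_params(f[1], f[2], f[3], mu),
    residual = best$deviance,
    converged = best$info %in% 1:4,
    n_restarts_used = used,
    non_identifiable = f[3] > 0.99), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (is.null(x$theta_hat)) {
    cat("<fit_result: optimiser failed on all starts>\n")
  } else {
    cat(sprintf("<fit_result: ndi %.3f odi %.3f fwf %.3f, rss %.3g, %s>\n",
                x$theta_hat$ndi, x$theta_hat$odi, x$theta_hat$fwf, x$residual,
                if (x$converged) "converged" else "not converged"))
  }
  invisible(x)
}

#' Fit many voxels
#'
#' @param voxels list of [voxel_data()] objects
#' @param ... passed on to [nlls_fit()]
#' @return n x 3 matrix of (ndi, odi, fwf) estimates
#' @export
nlls_fit_many <- function(voxels, ...) {
  out <- t(vapply(voxels, function(v) {
    f <- nlls_fit(v, ...)
    if (is.null(f$theta_hat)) return(c(NA_real_, NA_real_, NA_real_))
    c(f$theta_hat$ndi, f$theta_hat$odi, f$theta_hat$fwf)
  }, numeric(3)))
  colnames(out) <- c("ndi", "odi", "fwf")
  out
}

# Linear-layer layout of the point-set baseline, in unpack order.
pointnet_layout <- function() {
  blk <- function(name, out, input) data.frame(block = name, out = out, input = input)
  rbind(blk("t1_point", c(64, 128, 256), c(5, 64, 128)),
        blk("t1_fc", c(128, 64, 25), c(256, 128, 64)),
        blk("encoder1", c(64, 64), c(5, 64)),
        blk("t2_point", c(64, 128, 256), c(64, 64, 128)),
        blk("t2_fc", c(128, 64, 4096), c(256, 128, 64)),
        blk("encoder2", c(128, 1024), c(64, 128)),
        blk("head", c(2300, 256, 3), c(1024, 2300, 256)))
}

#' Point-set baseline network
#'
#' A PointNet-style architecture treating each mirrored measurement as an
#' independent point with features (qx, qy, qz, E, b): shared per-point
#' encoders with input and feature transform blocks (T-nets, initialised
#' to the identity), global max-pooling, and a fully connected head.
#' Batch normalisation is omitted. Permutation-invariant through the
#' max-pool, and reflection-invariant because inputs are antipodally
#' mirrored, but NOT rotation-invariant: raw coordinates enter the
#' encoder. About 3.5M learnable parameters (see
#' [pointnet_count_parameters()]).
#'
#' @param seed initialisation seed
#' @return an object of class `pointnet_model`
#' @export
pointnet_init <- function(seed = 1L) {
  lay <- pointnet_layout()
  w <- with_seed(seed, {
    unlist(lapply(seq_len(nrow(lay)), function(i) {
      # He-uniform weights (ReLU activations), zero biases
      a <- sqrt(6 / lay$input[i])
      v <- c(runif(lay$out[i] * lay$input[i], -a, a), rep(0, lay$out[i]))
      # T-net output layers start as the identity transform
      if ((lay$block[i] == "t1_fc" && lay$out[i] == 25) ||
          (lay$block[i] == "t2_fc" && lay$out[i] == 4096)) {
        d <- sqrt(lay$out[i])
        v <- c(rep(0, lay$out[i] * lay$input[i]), as.numeric(diag(d)))
      }
      v
    }))
  })
  structure(list(weights = as.numeric(w),
                 config = structure(list(k = NA_integer_), class = "pointnet_config"),
                 seed = seed),
            class = "pointnet_model")
}

#' @rdname pointnet_init
#' @param model optionally, a `pointnet_model` whose stored weights are
#'   counted
#' @return total learnable parameter count
#' @export
pointnet_count_parameters <- function(model = NULL) {
  if (!is.null(model)) return(length(model$weights))
  lay <- pointnet_layout()
  sum(lay$out * lay$input + lay$out)
}

#' @export
print.pointnet_model <- function(x, ...) {
  cat(sprintf("<pointnet_model: %d parameters%s>\n", length(x$weights),
              if (!is.null(x$trained) && x$trained) ", trained" else ""))
  invisible(x)
}

#' Run the point-set baseline
#'
#' @param model a `pointnet_model`
#' @param voxel a [voxel_data()]
#' @return named 3-vector of (ndi, odi, fwf) estimates
#' @export
pointnet_forward <- function(model, voxel) {
  stopifnot(inherits(model, "pointnet_model"), inherits(voxel, "voxel_data"))
  setNames(as.numeric(cpp_pn_predict(model$weights, list(as_cpp_voxel(voxel)))[1, ]),
           c("ndi", "odi", "fwf"))
}

#' @rdname pointnet_forward
#' @param object a `pointnet_model`
#' @param voxels list of [voxel_data()] objects
#' @param ... unused
#' @return n x 3 matrix of estimates
#' @export
predict.pointnet_model <- function(object, voxels, ...) {
  if (inherits(voxels, "voxel_data")) voxels <- list(voxels)
  out <- cpp_pn_predict(object$weights, lapply(voxels, as_cpp_voxel))
  colnames(out) <- c("ndi", "odi", "fwf")
  out
}
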