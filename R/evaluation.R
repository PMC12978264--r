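#' Test grid specification
#'
#' The evaluation grid: every combination of the given NDI/ODI/FWF values
#' (5^3 = 125 by default), each simulated `realisations` times with
#' independent noise and an independently drawn random fibre direction.
#' Default SNR follows the protocol being evaluated: 30 for DSI, 25 for
#' HCP, 20 for UKBB.
#'
#' @param values parameter values per axis
#' @param realisations independent noise realisations per grid point
#' @param snr b0 signal-to-noise ratio (`Inf` for noise-free)
#' @return an object of class `test_grid_spec`
#' @export
test_grid_spec <- function(values = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           realisations = 100, snr = 20) {
  structure(list(values = values, realisations = as.integer(realisations),
                 snr = snr), class = "test_grid_spec")
}

#' Default test SNR per evaluation protocol
#' @param label protocol label ("DSI", "HCP", "UKBB")
#' @return scalar SNR
#' @export
protocol_test_snr <- function(label) {
  switch(label, DSI = 30, HCP = 25, UKBB = 20,
         stop("no default SNR for protocol label '", label, "'"))
}

#' Generate a labelled test set
#'
#' Simulates `length(values)^3 * realisations` voxels under one protocol:
#' each grid point is simulated `realisations` times with independent
#' Rician noise and an independent uniformly random fibre direction.
#'
#' @param protocol a [protocol()]
#' @param spec a [test_grid_spec()]
#' @return an object of class `test_set`: `truth` (data frame with
#'   ndi/odi/fwf/mu columns), `signals` (n x N matrix), `protocol`, `spec`
#' @export
make_test_set <- function(protocol, spec = test_grid_spec()) {
  stopifnot(inherits(protocol, "protocol"), inherits(spec, "test_grid_spec"))
  grid <- expand.grid(ndi = spec$values, odi = spec$values, fwf = spec$values)
  n <- nrow(grid) * spec$realisations
  truth <- grid[rep(seq_len(nrow(grid)), each = spec$realisations), ]
  mu <- sample_sphere_directions(n)
  truth$mu_x <- mu[, 1]; truth$mu_y <- mu[, 2]; truth$mu_z <- mu[, 3]
  rownames(truth) <- NULL
  signals <- simulate_signals(protocol, truth)
  signals <- add_rician_noise(signals, spec$snr)
  structure(list(truth = truth, signals = signals, protocol = protocol,
                 spec = spec), class = "test_set")
}

#' @export
print.test_set <- function(x, ...) {
  cat(sprintf("<test_set: %d voxels on '%s' (snr %s)>\n", nrow(x$truth),
              x$protocol$label, format(x$spec$snr)))
  invisible(x)
}

#' Convert test-set rows to voxel lists
#'
#' @param test_set a [make_test_set()] result
#' @param idx row indices (default all)
#' @return list of [voxel_data()] objects
#' @export
test_set_voxels <- function(test_set, idx = seq_len(nrow(test_set$truth))) {
  lapply(idx, function(i) voxel_data(test_set$protocol, test_set$signals[i, ]))
}

#' Mean-squared-error report
#'
#' Per-parameter MSE over all voxels plus their mean ("total"), mirroring
#' how estimation accuracy is tabulated per protocol and method.
#'
#' @param predictions n x 3 matrix of (ndi, odi, fwf) estimates
#' @param truths n x 3 matrix or data frame of ground-truth values
#' @return an object of class `mse_report` with `per_parameter` (named
#'   vector) and `total`; total equals `mean(per_parameter)` exactly
#' @export
mse_report <- function(predictions, truths) {
  predictions <- as.matrix(predictions)
  truths <- as.matrix(as.data.frame(truths)[, c("ndi", "odi", "fwf")])
  if (nrow(predictions) != nrow(truths)) stop("predictions and truths differ in length")
  per <- colMeans((predictions - truths)^2)
  names(per) <- c("ndi", "odi", "fwf")
  structure(list(per_parameter = per, total = mean(per)), class = "mse_report")
}

#' @export
print.mse_report <- function(x, ...) {
  cat(sprintf("MSE  total %.3f | ndi %.3f  odi %.3f  fwf %.3f\n",
              x$total, x$per_parameter["ndi"], x$per_parameter["odi"],
              x$per_parameter["fwf"]))
  invisible(x)
}

#' Uniformly random rotation matrices
#'
#' Haar-uniform SO(3) samples via QR decomposition with sign fixing.
#'
#' @param n number of rotations
#' @return list of 3 x 3 rotation matrices (det + 1)
#' @export
random_rotations <- function(n) {
  lapply(seq_len(n), function(i) {
    qr_ <- qr(matrix(rnorm(9), 3))
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}

#' Rotation variance of an estimator
#'
#' Noise-free probe of orientation sensitivity: at every grid point the
#' underlying microstructure's fibre direction is rotated by each of
#' `n_rotations` random SO(3) rotations, the estimator is run, and the
#' standard deviation of each output parameter over the rotations is
#' computed. Returns the mean of these standard deviations over
#' parameters and grid points — 0 for any truly rotation-invariant
#' estimator.
#'
#' @param predict_fun function mapping a list of [voxel_data()] to an
#'   n x 3 estimate matrix (e.g. `function(v) predict(model, v)`)
#' @param protocol a [protocol()]
#' @param values grid values per parameter axis
#' @param n_rotations rotations per grid point
#' @param mu0 base fibre direction before rotation
#' @return scalar mean standard deviation
#' @export
rotation_variance <- function(predict_fun, protocol,
                              values = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              n_rotations = 100, mu0 = c(0, 0, 1)) {
  grid <- expand.grid(ndi = values, odi = values, fwf = values)
  rots <- random_rotations(n_rotations)
  mus <- t(vapply(rots, function(R) as.numeric(R %*% mu0), numeric(3)))
  sds <- vapply(seq_len(nrow(grid)), function(i) {
    tab <- grid[rep(i, n_rotations), ]
    tab$mu_x <- mus[, 1]; tab$mu_y <- mus[, 2]; tab$mu_z <- mus[, 3]
    sig <- simulate_signals(protocol, tab)
    vox <- lapply(seq_len(n_rotations), function(r) voxel_data(protocol, sig[r, ]))
    est <- predict_fun(vox)
    mean(apply(est, 2, sd))
  }, numeric(1))
  mean(sds)
}

#' Embedding principal-component spectrum
#'
#' Centred PCA of pooled embeddings; returns the cumulative fraction of
#' variance explained by the leading components.
#'
#' @param embeddings n x d matrix of embeddings (n > d)
#' @return numeric vector of length d of cumulative explained-variance
#'   ratios
#' @export
embedding_pca <- function(embeddings) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) <= ncol(embeddings)) {
    stop("need more embeddings than dimensions for a meaningful PCA")
  }
  p <- prcomp(embeddings, center = TRUE, scale. = FALSE)
  cumsum(p$sdev^2) / sum(p$sdev^2)
}
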