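#' Training configuration
#'
#' The supervised training regime: parameter sets are drawn from the
#' training prior, each paired with several random protocols; batches are
#' organised into groups of successive batches sharing the same parameter
#' sets under different protocols, with gradients accumulated over each
#' group before an Adam step. Rician noise (per-batch SNR) and measurement
#' dropout are applied freshly at every presentation, so no two
#' presentations are identical.
#'
#' @param n_voxels number of microstructure parameter sets
#' @param protocols_per_voxel random protocols per parameter set (also the
#'   number of batches per accumulation group)
#' @param epochs training epochs
#' @param batch_size voxels per batch
#' @param lr0 initial Adam learning rate
#' @param lr_decay multiplicative decay factor
#' @param lr_decay_every epochs between decay steps
#' @param grad_clip maximum global gradient norm
#' @param snr_range range of the per-batch uniform SNR draw
#' @param dropout_prob probability of applying measurement dropout to a
#'   presentation
#' @param dropout_frac_range range of the uniform dropped-fraction draw
#' @param seed base seed for dataset generation and the training stream
#' @return an object of class `training_config`
#' @export
training_config <- function(n_voxels = 10000, protocols_per_voxel = 10,
                            epochs = 500, batch_size = 10,
                            lr0 = 1e-3, lr_decay = 0.99, lr_decay_every = 5,
                            grad_clip = 1, snr_range = c(10, 40),
                            dropout_prob = 0.5, dropout_frac_range = c(0, 0.5),
                            seed = 1L) {
  stopifnot(n_voxels >= 1, protocols_per_voxel >= 1, batch_size >= 1)
  structure(list(n_voxels = as.integer(n_voxels),
                 protocols_per_voxel = as.integer(protocols_per_voxel),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr0 = lr0, lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 grad_clip = grad_clip, snr_range = snr_range,
                 dropout_prob = dropout_prob,
                 dropout_frac_range = dropout_frac_range,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Learning-rate schedule
#'
#' Stepped exponential decay: `lr0 * lr_decay^(epoch %/% lr_decay_every)`
#' with `epoch` counted from 0.
#'
#' @param epoch zero-based epoch index
#' @param config a [training_config()]
#' @return learning rate
#' @export
lr_schedule <- function(epoch, config) {
  config$lr0 * config$lr_decay^(epoch %/% config$lr_decay_every)
}

#' Variance of the training prior
#'
#' Per-parameter variance of U(0.025, 0.975), i.e. the MSE of the best
#' constant predictor — the sanity floor any successful training run must
#' beat by a wide margin.
#'
#' @return scalar variance (about 0.0752)
#' @export
prior_variance <- function() {
  (0.975 - 0.025)^2 / 12
}

#' Build the training dataset
#'
#' Samples `n_voxels` parameter sets from the prior and
#' `protocols_per_voxel` independent random multi-shell protocols for
#' each, then caches the noise-free forward signals per (parameters,
#' protocol) pair. Noise and dropout are never cached — they are applied
#' on the fly at every presentation during training.
#'
#' @param config a [training_config()]
#' @return an object of class `training_set`; `length(ts$examples)` equals
#'   `n_voxels * protocols_per_voxel`
#' @export
build_training_set <- function(config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  with_seed(config$seed, {
    params <- sample_params(config$n_voxels)
    P <- config$protocols_per_voxel
    examples <- vector("list", config$n_voxels * P)
    for (v in seq_len(config$n_voxels)) {
      for (p in seq_len(P)) {
        proto <- sample_training_protocol()
        s <- simulate_signals(proto, params[v, , drop = FALSE])[1, ]
        examples[[(v - 1) * P + p]] <-
          list(q = t(proto$q), b = proto$b, s = s,
               isb0 = as.numeric(proto$b == 0),
               theta = as.numeric(params[v, c("ndi", "odi", "fwf")]))
      }
    }
    structure(list(params = params, examples = examples,
                   n_voxels = config$n_voxels, protocols_per_voxel = P),
              class = "training_set")
  })
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set: %d voxels x %d protocols = %d examples>\n",
              x$n_voxels, x$protocols_per_voxel, length(x$examples)))
  invisible(x)
}

#' Grouped batch schedule for one epoch
#'
#' Shuffles parameter sets into groups of `batch_size` voxels. Each group
#' yields `protocols_per_voxel` successive batches: batch t presents the
#' group's voxels under their t-th protocol, so all batches of a group
#' share ground-truth parameters while protocols differ. One optimiser
#' step is taken per group (gradient accumulation). Incomplete trailing
#' groups are dropped.
#'
#' @param dataset a [build_training_set()] result
#' @param batch_size voxels per batch
#' @return list of batch_size x protocols_per_voxel integer matrices of
#'   example indices; each matrix column is one batch
#' @export
grouped_batch_schedule <- function(dataset, batch_size = 10) {
  stopifnot(inherits(dataset, "training_set"))
  P <- dataset$protocols_per_voxel
  vox <- sample(dataset$n_voxels)
  n_groups <- dataset$n_voxels %/% batch_size
  lapply(seq_len(n_groups), function(gi) {
    v <- vox[((gi - 1) * batch_size + 1):(gi * batch_size)]
    outer(v - 1L, seq_len(P) - 1L, function(a, b) a * P + b + 1L)
  })
}

#' Randomly drop measurements from a voxel
#'
#' With probability `prob`, removes floor(f * N_dwi) uniformly chosen
#' diffusion-weighted measurements, f ~ U over `frac_range`. b = 0
#' measurements are never dropped and at least one DWI is always kept, so
#' normalisation and graph construction always remain possible.
#'
#' @param voxel a [voxel_data()]
#' @param prob probability of applying dropout at all
#' @param frac_range range of the dropped fraction
#' @return a [voxel_data()] (possibly the input unchanged)
#' @export
measurement_dropout <- function(voxel, prob = 0.5, frac_range = c(0, 0.5)) {
  stopifnot(inherits(voxel, "voxel_data"))
  if (runif(1) >= prob) return(voxel)
  f <- runif(1, frac_range[1], frac_range[2])
  p <- voxel$protocol
  dwi <- which(p$b > 0)
  nd <- floor(f * length(dwi))
  if (nd >= length(dwi)) nd <- length(dwi) - 1
  if (nd < 1) return(voxel)
  drop <- sample(dwi, nd)
  keep <- sort(setdiff(seq_len(p$n), drop))
  voxel_data(protocol(p$b[keep], p$g[keep, , drop = FALSE], p$label),
             voxel$signals[keep])
}

train_loop <- function(model, dataset, config, epoch_fun, verbose) {
  set.seed(config$seed + 1L)
  nw <- length(model$weights)
  w <- model$weights; m <- numeric(nw); v <- numeric(nw); t <- 0L
  trace <- numeric(config$epochs)
  conf_base <- list(k = if (!is.null(model$config$k)) model$config$k else 8L,
                    clip = config$grad_clip,
                    snr_lo = config$snr_range[1], snr_hi = config$snr_range[2],
                    drop_p = config$dropout_prob,
                    drop_lo = config$dropout_frac_range[1],
                    drop_hi = config$dropout_frac_range[2])
  for (e in seq_len(config$epochs)) {
    groups <- grouped_batch_schedule(dataset, config$batch_size)
    conf <- c(conf_base, list(lr = lr_schedule(e - 1, config)))
    res <- epoch_fun(w, m, v, t, dataset$examples, groups, conf)
    if (!is.finite(res$loss)) {
      stop(sprintf("non-finite training loss at epoch %d (lr %.2e); aborting",
                   e, conf$lr))
    }
    w <- as.numeric(res$w); m <- as.numeric(res$m)
    v <- as.numeric(res$v); t <- res$t
    trace[e] <- res$loss
    if (verbose) message(sprintf("epoch %3d  loss %.5f  lr %.2e", e, res$loss, conf$lr))
  }
  model$weights <- w
  model$trained <- TRUE
  model$loss_trace <- trace
  model$training <- unclass(config)
  model
}

#' Train the graph network
#'
#' Runs the full regime from [training_config()]: per-epoch reshuffled
#' grouped batches, fresh Rician noise with per-batch SNR, fresh
#' measurement dropout per presentation, mean-squared-error loss over the
#' three parameters, Adam with stepped learning-rate decay, global
#' gradient-norm clipping, one step per accumulation group. Deterministic
#' given the seeds (up to floating-point reduction order).
#'
#' @param model a [gnn_init()] model
#' @param dataset a [build_training_set()] result
#' @param config a [training_config()]
#' @param verbose print per-epoch loss
#' @return the trained `gnn_model` with `loss_trace` attached
#' @export
train_gnn <- function(model, dataset, config, verbose = FALSE) {
  stopifnot(inherits(model, "gnn_model"), inherits(dataset, "training_set"))
  train_loop(model, dataset, config, cpp_gnn_epoch, verbose)
}

#' @rdname train_gnn
#' @export
train_pointnet <- function(model, dataset, config, verbose = FALSE) {
  stopifnot(inherits(model, "pointnet_model"), inherits(dataset, "training_set"))
  train_loop(model, dataset, config, cpp_pn_epoch, verbose)
}
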