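#' Network architecture configuration
#'
#' The fixed architecture of the invariant message-passing network: three
#' message-passing layers with edge MLPs d_in-64-64-16 (layer 1 consumes
#' the 2 node features of the source plus the 3 edge features; later
#' layers consume the 16-dim node state only), node MLPs
#' (d_state + 16)-64-64-16, a 16-16-1 attention MLP for softmax pooling
#' and a 16-32-3 readout, SiLU activations on hidden layers. The default
#' instantiation has exactly 40,132 learnable scalars.
#'
#' @param k neighbour count used when building input graphs
#' @return an object of class `gnn_config`
#' @export
gnn_config <- function(k = 8) {
  structure(list(k = as.integer(k), n_layers = 3L, state_dim = 16L,
                 hidden = 64L), class = "gnn_config")
}

# Linear-layer layout of the flat weight vector, in unpack order.
# Must match the C++ Reader exactly.
gnn_layout <- function() {
  mlp3 <- function(block, d_in) {
    data.frame(block = block, out = c(64, 64, 16), input = c(d_in, 64, 64))
  }
  rbind(mlp3("edge1", 5), mlp3("node1", 18),
        mlp3("edge2", 16), mlp3("node2", 32),
        mlp3("edge3", 16), mlp3("node3", 32),
        data.frame(block = "attention", out = c(16, 1), input = c(16, 16)),
        data.frame(block = "readout", out = c(32, 3), input = c(16, 32)))
}

#' Parameter counts of the network
#'
#' `gnn_block_sizes()` gives learnable-scalar counts per architectural
#' block (weights plus biases); `gnn_count_parameters()` their total.
#'
#' @return named integer vector / single integer
#' @export
gnn_block_sizes <- function() {
  lay <- gnn_layout()
  sz <- tapply(lay$out * lay$input + lay$out, lay$block, sum)
  out <- sz[unique(lay$block)]
  setNames(as.integer(out), unique(lay$block))
}

#' @rdname gnn_block_sizes
#' @param model optionally, a `gnn_model` whose stored weight vector is
#'   counted instead of the architectural formula
#' @export
gnn_count_parameters <- function(model = NULL) {
  if (!is.null(model)) return(length(model$weights))
  sum(gnn_block_sizes())
}

#' Initialise the network
#'
#' Variance-preserving fan-in uniform initialisation: each linear layer's
#' weights are drawn from U(-a, a) with a = 1.5 sqrt(3 / d_in) and biases
#' start at zero. The gain of 1.5 compensates the contraction of the SiLU
#' nonlinearity in its small-activation regime so that input differences
#' survive the deep message-passing stack at initialisation (see the
#' methods vignette); smaller gains collapse the embedding to a constant,
#' larger ones make early optimisation unstable.
#'
#' @param seed integer initialisation seed
#' @param config a [gnn_config()]
#' @param gain initialisation gain
#' @return an object of class `gnn_model` holding the flat weight vector
#' @export
gnn_init <- function(seed = 1L, config = gnn_config(), gain = 1.5) {
  lay <- gnn_layout()
  w <- with_seed(seed, {
    unlist(lapply(seq_len(nrow(lay)), function(i) {
      a <- gain * sqrt(3 / lay$input[i])
      c(runif(lay$out[i] * lay$input[i], -a, a), rep(0, lay$out[i]))
    }))
  })
  structure(list(weights = as.numeric(w), config = config, seed = seed),
            class = "gnn_model")
}

#' @export
print.gnn_model <- function(x, ...) {
  cat(sprintf("<gnn_model: %d parameters, k = %d%s>\n", length(x$weights),
              x$config$k,
              if (!is.null(x$trained) && x$trained) ", trained" else ""))
  invisible(x)
}

#' Run the network on one voxel
#'
#' Builds the mirrored k-NN graph from the voxel's own protocol and runs
#' the forward pass. By construction the output is invariant to
#' permutations of the measurements and to O(3) transforms of the
#' gradient directions, and accepts any number of measurements.
#'
#' @param model a `gnn_model`
#' @param voxel a [voxel_data()]
#' @return list with `theta` (named NDI/ODI/FWF estimates) and `z`
#'   (the 16-dim pooled embedding)
#' @export
gnn_forward <- function(model, voxel) {
  stopifnot(inherits(model, "gnn_model"), inherits(voxel, "voxel_data"))
  out <- cpp_gnn_predict(model$weights, list(as_cpp_voxel(voxel)),
                         model$config$k)
  list(theta = setNames(as.numeric(out$theta[1, ]), c("ndi", "odi", "fwf")),
       z = as.numeric(out$z[1, ]))
}

#' Predict microstructure for many voxels
#'
#' @param object a `gnn_model`
#' @param voxels a list of [voxel_data()] objects (or a single one)
#' @param type `"theta"` for an n x 3 matrix of parameter estimates,
#'   `"embedding"` for the n x 16 pooled embeddings
#' @param ... unused
#' @return numeric matrix
#' @export
predict.gnn_model <- function(object, voxels, type = c("theta", "embedding"), ...) {
  type <- match.arg(type)
  if (inherits(voxels, "voxel_data")) voxels <- list(voxels)
  out <- cpp_gnn_predict(object$weights, lapply(voxels, as_cpp_voxel),
                         object$config$k)
  if (type == "theta") {
    colnames(out$theta) <- c("ndi", "odi", "fwf")
    out$theta
  } else {
    out$z
  }
}

#' Run the network on a prebuilt graph
#'
#' Mostly useful for testing the pipeline stages separately; equivalent to
#' [gnn_forward()] when the graph came from [build_graph()].
#'
#' @param model a `gnn_model`
#' @param graph a [build_graph()] result
#' @return list with `theta` and `z`
#' @export
gnn_forward_graph <- function(model, graph) {
  stopifnot(inherits(graph, "qgraph"))
  out <- cpp_gnn_forward_graph(model$weights, graph$node_features,
                               graph$edges, graph$edge_features)
  list(theta = setNames(as.numeric(out$theta), c("ndi", "odi", "fwf")),
       z = as.numeric(out$z))
}

#' Save or load a model checkpoint
#'
#' Self-describing JSON archive: architecture configuration, weights,
#' seeds and (if present) the training configuration and loss trace.
#'
#' @param model a `gnn_model` or `pointnet_model`
#' @param path file path (`.json`)
#' @return `load_checkpoint()` returns the model object
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(class = class(model)[1],
                  config = unclass(model$config),
                  seed = model$seed,
                  trained = isTRUE(model$trained),
                  training = model$training,
                  loss_trace = model$loss_trace,
                  weights = model$weights)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- p$class
  config <- structure(as.list(p$config),
                      class = if (cls == "gnn_model") "gnn_config" else "pointnet_config")
  structure(list(weights = as.numeric(p$weights), config = config,
                 seed = p$seed, trained = isTRUE(p$trained),
                 training = p$training, loss_trace = p$loss_trace),
            class = cls)
}
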