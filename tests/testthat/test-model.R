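# Network architecture, invariances, gradients, checkpoints

test_that("architecture audit: per-block and total parameter counts", {
  sizes <- gnn_block_sizes()
  expect_equal(unname(sizes["edge1"]), 5584)      # (5*64+64)+(64*64+64)+(64*16+16)
  expect_equal(unname(sizes["node1"]), 6416)
  expect_equal(unname(sizes["edge2"]), 6288)
  expect_equal(unname(sizes["node2"]), 7312)
  expect_equal(unname(sizes["edge3"]), 6288)
  expect_equal(unname(sizes["node3"]), 7312)
  expect_equal(unname(sizes["attention"]), 289)   # (16*16+16)+(16*1+1)
  expect_equal(unname(sizes["readout"]), 643)     # (16*32+32)+(32*3+3)
  expect_equal(gnn_count_parameters(), 40132)
  # instantiated weight vector has exactly that many scalars
  expect_equal(gnn_count_parameters(gnn_init(1)), 40132)
})

test_that("forward output is a finite 3-vector across protocols and sizes", {
  m <- gnn_init(2)
  tab <- params_table(default_params())
  for (proto in list(hcp_protocol(), ukbb_protocol(), tiny_protocol())) {
    set.seed(3)
    vox <- voxel_data(proto, add_rician_noise(simulate_signals(proto, tab)[1, ], 20))
    f <- gnn_forward(m, vox)
    expect_length(f$theta, 3)
    expect_true(all(is.finite(f$theta)))
    expect_length(f$z, 16)
    expect_true(all(is.finite(f$z)))
  }
  # minimum viable voxel: one DWI + one b0
  p <- protocol(c(0, 1), rbind(c(0, 0, 0), c(0, 0, 1)))
  expect_true(all(is.finite(gnn_forward(m, voxel_data(p, c(1, 0.5)))$theta)))
})

test_that("forward is invariant under permutation, O(3), and sign flips", {
  set.seed(19)
  for (model in list(gnn_init(2), quick_trained_gnn())) {
    proto <- tiny_protocol(n_per_shell = 20)
    vox <- simulate_voxel(proto, default_params(c(1, -2, 0.5)), snr = 25)
    f0 <- gnn_forward(model, vox)
    # permutations: identical graph, bit-identical output
    for (i in 1:3) {
      fp <- gnn_forward(model, permute_voxel(vox, sample(proto$n)))
      expect_identical(fp$theta, f0$theta)
      expect_identical(fp$z, f0$z)
    }
    # rotations and reflections of q
    for (Q in c(random_rotations(3), list(diag(c(-1, 1, 1)), -diag(3)))) {
      fq <- gnn_forward(model, voxel_data(rotate_protocol(proto, Q), vox$signals))
      expect_equal(fq$theta, f0$theta, tolerance = 1e-5)
    }
    # sign flip of a subset of directions: graph unchanged exactly
    flip <- c(rep(1, proto$n - 10), rep(-1, 10))
    vf <- voxel_data(protocol(proto$b, proto$g * flip), vox$signals)
    expect_identical(gnn_forward(model, vf)$theta, f0$theta)
  }
})

test_that("forward through a prebuilt graph equals the direct path", {
  set.seed(21)
  m <- gnn_init(4)
  vox <- simulate_voxel(ukbb_protocol(), default_params(), snr = 20)
  f1 <- gnn_forward(m, vox)
  f2 <- gnn_forward_graph(m, build_graph(vox, graph_config(k = m$config$k)))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$z, f2$z)
})

test_that("analytic gradients match finite differences", {
  set.seed(22)
  # moderate-gain weights keep the loss surface locally smooth enough for
  # second-order-accurate finite differences in float32
  m <- gnn_init(3, gain = 1.1)
  vox <- simulate_voxel(tiny_protocol(), default_params(), snr = 20)
  cv <- noddigraph:::as_cpp_voxel(vox)
  tgt <- c(0.5, 0.4, 0.2)
  lg <- noddigraph:::cpp_gnn_loss_grad(m$weights, cv, 8L, tgt)
  expect_true(is.finite(lg$loss))
  # directional derivative along the gradient
  d <- lg$grad / sqrt(sum(lg$grad^2))
  h <- 1e-2
  fd <- (noddigraph:::cpp_gnn_loss_grad(m$weights + h * d, cv, 8L, tgt)$loss -
         noddigraph:::cpp_gnn_loss_grad(m$weights - h * d, cv, 8L, tgt)$loss) / (2 * h)
  expect_equal(fd, sum(lg$grad * d), tolerance = 1e-3)
  # the largest individual weight gradients
  idx <- order(-abs(lg$grad))[1:8]
  for (i in idx) {
    wp <- m$weights; wp[i] <- wp[i] + h
    wm <- m$weights; wm[i] <- wm[i] - h
    fd_i <- (noddigraph:::cpp_gnn_loss_grad(wp, cv, 8L, tgt)$loss -
             noddigraph:::cpp_gnn_loss_grad(wm, cv, 8L, tgt)$loss) / (2 * h)
    expect_equal(fd_i, lg$grad[i], tolerance = 5e-3)
  }
})

test_that("attention pooling is a symmetric convex combination", {
  # degenerate graphs where every node carries identical features and an
  # identical neighbourhood: softmax weights must be uniform, so the
  # pooled embedding equals the single-node case regardless of node count
  m <- gnn_init(6)
  one_node <- structure(list(
    node_features = matrix(c(0.6, 1), 1, 2,
                           dimnames = list(NULL, c("E", "b"))),
    positions = matrix(c(0, 0, 1), 1, 3),
    edges = matrix(c(1L, 1L), 1, 2), M = 1L,
    edge_features = matrix(c(0, 1, 0), 1, 3)), class = "qgraph")
  many <- structure(list(
    node_features = matrix(rep(c(0.6, 1), each = 5), 5, 2,
                           dimnames = list(NULL, c("E", "b"))),
    positions = matrix(rep(c(0, 0, 1), each = 5), 5, 3),
    edges = cbind(1:5, 1:5), M = 5L,
    edge_features = matrix(rep(c(0, 1, 0), each = 5), 5, 3)), class = "qgraph")
  f1 <- gnn_forward_graph(m, one_node)
  f5 <- gnn_forward_graph(m, many)
  expect_equal(f5$z, f1$z, tolerance = 1e-5)
  expect_equal(f5$theta, f1$theta, tolerance = 1e-5)
  # doubling the neighbour multiset of identical messages leaves the mean
  # aggregate unchanged
  doubled <- many
  doubled$edges <- rbind(many$edges, many$edges)
  doubled$edge_features <- rbind(many$edge_features, many$edge_features)
  fd <- gnn_forward_graph(m, doubled)
  expect_equal(fd$theta, f5$theta, tolerance = 1e-5)
})

test_that("checkpoints round-trip through JSON", {
  m <- quick_trained_gnn()
  path <- tempfile(fileext = ".json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_s3_class(m2, "gnn_model")
  # JSON text serialisation preserves weights to ~15 significant digits,
  # identical at the float32 resolution the network computes in
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(m2$config$k, m$config$k)
  set.seed(30)
  vox <- simulate_voxel(tiny_protocol(), default_params(), snr = 20)
  expect_identical(gnn_forward(m, vox)$theta, gnn_forward(m2, vox)$theta)
})
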