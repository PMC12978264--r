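# Graph construction: normalisation, mirroring, k-NN, invariant features

test_that("signal normalisation divides by the mean b0", {
  p <- protocol(c(0, 1), rbind(c(0, 0, 0), c(0, 0, 1)))
  v <- voxel_data(p, c(100, 50))
  expect_equal(normalise_signals(v), c(1, 0.5))
  # two b0s: mean normaliser
  p2 <- protocol(c(0, 0, 1), rbind(0, 0, c(0, 0, 1)))
  v2 <- voxel_data(p2, c(90, 110, 50))
  expect_equal(normalise_signals(v2)[3], 0.5)
  # scale invariance
  v3 <- voxel_data(p2, c(90, 110, 50) * 17.3)
  expect_equal(normalise_signals(v3), normalise_signals(v2))
  # all equal -> all one
  v4 <- voxel_data(p2, rep(42, 3))
  expect_equal(normalise_signals(v4), rep(1, 3))
  # missing b0
  p5 <- protocol(c(1, 2), rbind(c(0, 0, 1), c(0, 1, 0)))
  expect_error(normalise_signals(voxel_data(p5, c(1, 1))), "b = 0")
})

test_that("mirroring drops b0s, pairs antipodes, and is closed under negation", {
  set.seed(8)
  vox <- simulate_voxel(ukbb_protocol(), default_params(), snr = 20)
  mp <- mirror_points(vox)
  expect_equal(nrow(mp$positions), 200)  # 2 * (102 - 2)
  # closed under negation: -positions is the same set
  key <- function(m) paste(round(m[, 1], 9), round(m[, 2], 9), round(m[, 3], 9))
  expect_setequal(key(-mp$positions), key(mp$positions))
  # minimal case: 1 DWI + 1 b0 -> two antipodal nodes with equal E
  p <- protocol(c(0, 1), rbind(c(0, 0, 0), c(0, 0, 1)))
  mp2 <- mirror_points(voxel_data(p, c(1, 0.4)))
  expect_equal(nrow(mp2$positions), 2)
  expect_equal(mp2$positions[1, ], -mp2$positions[2, ])
  expect_equal(mp2$E, c(0.4, 0.4))
})

test_that("k-NN edges: caps, no self-loops, rotation invariance", {
  # two antipodal nodes, k capped at M - 1 -> one mutual pair
  pos2 <- rbind(c(0, 0, 1), c(0, 0, -1))
  e2 <- knn_edges(pos2, graph_config(k = 8))
  expect_equal(unname(e2), rbind(c(1L, 2L), c(2L, 1L)))
  set.seed(12)
  pos <- matrix(rnorm(60), 20, 3)
  e <- knn_edges(pos, graph_config(k = 4))
  expect_true(all(e[, 1] != e[, 2]))
  # union symmetrisation: edge set closed under reversal
  expect_setequal(paste(e[, 1], e[, 2]), paste(e[, 2], e[, 1]))
  # every node has at least k neighbours after union
  expect_true(all(table(e[, 1]) >= 4))
  # orthogonal transforms preserve the edge list
  for (Q in random_rotations(2)) {
    expect_identical(knn_edges(pos %*% t(Q), graph_config(k = 4)), e)
  }
  refl <- diag(c(-1, 1, 1))
  expect_identical(knn_edges(pos %*% refl, graph_config(k = 4)), e)
  expect_error(knn_edges(pos[1, , drop = FALSE], graph_config()), "two nodes")
})

test_that("edge features take the documented values and invariances", {
  expect_equal(unname(edge_features(c(1, 0, 0), c(0, 1, 0), 1, 1)),
               matrix(c(sqrt(2), 0, 0), 1))
  expect_equal(unname(edge_features(c(1, 0, 0), c(-1, 0, 0), 1, 1)),
               matrix(c(2, 1, 0), 1))
  expect_equal(unname(edge_features(c(1, 0, 0), c(sqrt(2), 0, 0), 1, 2)),
               matrix(c(sqrt(2) - 1, 1, -1), 1))
  expect_error(edge_features(c(0, 0, 0), c(1, 0, 0), 0, 1), "origin")
  # joint orthogonal transform leaves dist and |cos| unchanged
  set.seed(9)
  qi <- matrix(rnorm(30), 10); qj <- matrix(rnorm(30), 10)
  f0 <- edge_features(qi, qj, 1, 2)
  for (Q in random_rotations(3)) {
    expect_equal(edge_features(qi %*% t(Q), qj %*% t(Q), 1, 2), f0,
                 tolerance = 1e-12)
  }
})

test_that("build_graph composes the stages and matches the R pipeline", {
  set.seed(14)
  vox <- simulate_voxel(ukbb_protocol(), default_params(), snr = 20)
  g <- build_graph(vox)
  expect_s3_class(g, "qgraph")
  expect_equal(g$M, 200)
  expect_gte(nrow(g$edges), 200 * 8)
  expect_true(all(g$edges[, 1] != g$edges[, 2]))
  # node features expose only (E, b), never raw signals
  expect_equal(colnames(g$node_features), c("E", "b"))
  expect_true(all(g$node_features[, "E"] < 2))
  # independent R-level pipeline gives the same graph
  mp <- mirror_points(vox)
  expect_equal(mp$positions, g$positions, tolerance = 1e-14, ignore_attr = TRUE)
  e <- knn_edges(mp$positions, graph_config())
  expect_true(all(e == g$edges))
  ef <- edge_features(mp$positions[e[, 1], ], mp$positions[e[, 2], ],
                      mp$b[e[, 1]], mp$b[e[, 2]])
  expect_equal(unname(ef), unname(g$edge_features), tolerance = 1e-12)
})

test_that("graphs are invariant to permutation, sign flips, and O(3)", {
  set.seed(15)
  proto <- tiny_protocol()
  vox <- simulate_voxel(proto, default_params(c(0.2, 0.9, -0.1)), snr = 15)
  g0 <- build_graph(vox)
  # permutation of measurements: identical graph after canonical ordering
  perm <- sample(proto$n)
  expect_equal(build_graph(permute_voxel(vox, perm)), g0)
  # negating all q: identical graph (node set closed under negation)
  vneg <- voxel_data(protocol(proto$b, -proto$g), vox$signals)
  expect_equal(build_graph(vneg), g0)
  # O(3) transforms: same graph up to the relabelling induced by the
  # coordinate-dependent canonical node order
  for (Q in c(random_rotations(2), list(diag(c(1, -1, 1))))) {
    gq <- build_graph(voxel_data(rotate_protocol(proto, Q), vox$signals))
    # match nodes by rotated position
    rot_pos <- g0$positions %*% t(Q)
    map <- integer(g0$M)
    for (i in seq_len(g0$M)) {
      d <- rowSums((gq$positions - rep(rot_pos[i, ], each = g0$M))^2)
      map[i] <- which.min(d)
      expect_lt(min(d), 1e-12)
    }
    expect_true(!any(duplicated(map)))
    expect_equal(gq$node_features[map, ], g0$node_features, tolerance = 1e-9)
    ekey <- function(e) paste(e[, 1], e[, 2])
    expect_setequal(ekey(cbind(map[g0$edges[, 1]], map[g0$edges[, 2]])),
                    ekey(gq$edges))
    # edge features agree edge-by-edge under the mapping
    ord0 <- order(map[g0$edges[, 1]], map[g0$edges[, 2]])
    ordq <- order(gq$edges[, 1], gq$edges[, 2])
    expect_equal(unname(gq$edge_features[ordq, ]),
                 unname(g0$edge_features[ord0, ]), tolerance = 1e-6)
  }
})

test_that("graph serialisation writes node and edge tables", {
  set.seed(16)
  vox <- simulate_voxel(tiny_protocol(), default_params(), snr = 30)
  g <- build_graph(vox)
  np <- tempfile(fileext = ".csv"); ep <- tempfile(fileext = ".csv")
  write_qgraph(g, np, ep)
  nodes <- read.csv(np); edges <- read.csv(ep)
  expect_equal(nrow(nodes), g$M)
  expect_equal(nrow(edges), nrow(g$edges))
  expect_equal(nodes$E, unname(g$node_features[, "E"]))
})
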