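test_that("spatial kNN matches lattice geometry and a brute-force oracle", {
  # interior point of a unit lattice: k = 4 gives the orthogonal cross
  g5 <- expand.grid(x = 0:4, y = 0:4)
  coords <- as.matrix(g5)
  gr <- build_spatial_knn(coords, k = 4)
  centre <- which(g5$x == 2 & g5$y == 2)
  expected <- which(abs(g5$x - 2) + abs(g5$y - 2) == 1)
  expect_setequal(gr$knn[centre, ], expected)

  # 3 collinear equally spaced points, k = 1
  line <- build_spatial_knn(cbind(c(0, 1, 2), 0), k = 1)
  expect_equal(line$edges, cbind(c(1, 2), c(2, 3)), ignore_attr = TRUE)

  # random points vs O(n^2) oracle
  set.seed(5)
  pts <- matrix(runif(400), 200, 2)
  gr2 <- build_spatial_knn(pts, k = 6)
  expect_equal(gr2$knn, brute_knn(pts, 6))

  # rigid motion invariance of the edge set
  th <- 0.7
  rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) +
    matrix(c(3, -1), 200, 2, byrow = TRUE)
  expect_equal(build_spatial_knn(rot, k = 6)$edges, gr2$edges)

  expect_error(build_spatial_knn(pts[1:3, ], k = 3), "below")
})

test_that("pairwise edge weights match closed forms and are symmetric", {
  Y <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1), c(1, 2, 4), c(2, 2, 5))
  expect_equal(edge_weight_pearson(Y, 1, 2), 1.0)
  expect_equal(edge_weight_pearson(Y, 1, 3), -1.0)
  expect_equal(edge_weight_pearson(Y, 4, 5), 0.944911182523068)
  expect_equal(edge_weight_pearson(Y, 5, 4), edge_weight_pearson(Y, 4, 5))
  expect_warning(w0 <- edge_weight_pearson(rbind(c(1, 1, 1), c(1, 2, 3)),
                                           1, 2), "constant")
  expect_equal(w0, 0)

  # SNN: identical rows share the full neighbour set
  set.seed(2)
  Z <- rbind(matrix(rnorm(40, mean = 0), 20, 2),
             matrix(rnorm(40, mean = 50), 20, 2))
  Z[2, ] <- Z[1, ]
  expect_equal(edge_weight_snn(Z, 1, 2, k_snn = 5), 1.0)
  # far-separated clusters share nothing
  expect_equal(edge_weight_snn(Z, 3, 25, k_snn = 5), 0.0)

  # brute-force set-intersection oracle on a 50-point fixture
  # (self-inclusive sets: the point plus its k-1 nearest others)
  set.seed(3)
  W <- matrix(rnorm(150), 50, 3)
  nn <- cbind(1:50, brute_knn(W, 6))
  for (pair in list(c(1, 2), c(10, 40), c(25, 26))) {
    expect_equal(edge_weight_snn(W, pair[1], pair[2], k_snn = 7),
                 length(intersect(nn[pair[1], ], nn[pair[2], ])) / 7)
  }
})

test_that("smoothed weights reduce to pairwise at q = 0 and match brute force", {
  set.seed(4)
  coords <- matrix(runif(60, 0, 10), 30, 2)
  Y <- matrix(rnorm(30 * 5), 30, 5)
  gr <- build_spatial_knn(coords, k = 4)

  w0 <- smoothed_edge_weights(gr, Y, q = 0)
  wp <- nicheMNN:::pearson_rows(Y, gr$edges[, 1], gr$edges[, 2])
  expect_equal(w0, wp)

  wq <- smoothed_edge_weights(gr, Y, q = 4)
  oracle <- vapply(seq_len(nrow(gr$edges)), function(i)
    smoothed_weight_oracle(coords, Y, gr$edges[i, 1], gr$edges[i, 2], 4), 0)
  expect_equal(wq, oracle, tolerance = 1e-12)

  # two spatially separated homogeneous blobs with identical expression:
  # the across-gap edge averages two identical mean vectors
  cb <- rbind(cbind(runif(10), runif(10)), cbind(runif(10) + 100, runif(10)))
  Yb <- matrix(rep(c(1, 5, 2, 4), each = 20), 20, 4)
  Yb <- Yb + 0  # identical rows everywhere
  grb <- build_spatial_knn(cb, k = 3)
  wb <- smoothed_edge_weights(grb, Yb, q = 3)
  expect_true(all(wb == 1))
})

test_that("pruning keeps exactly the >= threshold edges, monotone in threshold", {
  set.seed(6)
  coords <- matrix(runif(80), 40, 2)
  gr <- build_spatial_knn(coords, k = 4)
  w <- runif(nrow(gr$edges), -1, 1)
  gr$weights <- w

  none <- prune_edges(gr, threshold = -1)
  expect_equal(nrow(none$edges), nrow(gr$edges))
  empty <- prune_edges(gr, threshold = max(w) + 0.1)
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(attr(empty, "prune_report")$n_removed, length(w))

  mid <- prune_edges(gr, threshold = 0.2)
  expect_equal(mid$edges, gr$edges[w >= 0.2, , drop = FALSE])

  sizes <- vapply(seq(-1, 1, by = 0.1), function(th)
    nrow(prune_edges(gr, th)$edges), 0L)
  expect_true(all(diff(sizes) <= 0))
})
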