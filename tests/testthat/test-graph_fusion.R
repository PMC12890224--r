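test_that("KNN kernel graph matches hand-evaluated values and handles edge cases", {
  # 3 samples on a line at 0, 1, 3; K=1, mu=0.3: pairwise d2 {1,4,9},
  # delta_sq = 4, nearest neighbour of sample 1 is sample 2
  X <- matrix(c(0, 1, 3), 3, 1)
  A <- knn_kernel_graph(X, K = 1, mu = 0.3)
  expect_equal(attr(A, "delta_sq"), 4)
  expect_equal(A[1, 2], exp(-1 / 1.2), tolerance = 1e-10)
  expect_equal(A[2, 1], A[1, 2])      # symmetrized
  expect_equal(A[1, 3], 0)            # not a K=1 neighbour in either direction
  expect_equal(A[2, 3], exp(-4 / 1.2), tolerance = 1e-10)
  expect_equal(diag(A), rep(0, 3))

  # coincident samples yield kernel weight exactly 1
  Xc <- matrix(c(0, 0, 5, 9), 4, 1)
  Ac <- knn_kernel_graph(Xc, K = 1, mu = 0.3)
  expect_equal(Ac[1, 2], 1)

  # K = n-1 makes every off-diagonal entry positive
  set.seed(4)
  Xf <- matrix(rnorm(12), 6, 2)
  Af <- knn_kernel_graph(Xf, K = 5, mu = 0.3)
  expect_true(all(Af[upper.tri(Af)] > 0))
  expect_true(all(Af >= 0 & Af <= 1))

  # identical samples: degenerate distances are fatal
  expect_error(knn_kernel_graph(matrix(1, 5, 2), K = 2, mu = 0.3),
               "degenerate")
})

test_that("KNN graph is invariant to feature permutation, equivariant to sample permutation, monotone in mu", {
  set.seed(11)
  X <- matrix(rnorm(60), 12, 5)
  A <- knn_kernel_graph(X, K = 3, mu = 0.3)
  expect_equal(unclass(knn_kernel_graph(X[, c(4, 2, 5, 1, 3)], K = 3, mu = 0.3)),
               unclass(A), tolerance = 1e-12, ignore_attr = TRUE)
  perm <- sample(12)
  Ap <- knn_kernel_graph(X[perm, ], K = 3, mu = 0.3)
  expect_equal(unclass(Ap), unclass(A[perm, perm]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # larger mu inflates every nonzero kernel weight (same delta_sq)
  A2 <- knn_kernel_graph(X, K = 3, mu = 0.6)
  nz <- A > 0
  expect_true(all(A2[nz] > A[nz]))
})

test_that("graph fusion averages adjacencies over the union of edges", {
  A1 <- matrix(0, 3, 3); A2 <- matrix(0, 3, 3)
  A1[1, 2] <- A1[2, 1] <- 0.4
  A2[1, 2] <- A2[2, 1] <- 0.6
  A1[1, 3] <- A1[3, 1] <- 0.4          # edge present only in A1
  F <- fuse_graphs(list(A1, A2))
  expect_equal(F[1, 2], 0.5)
  expect_equal(F[1, 3], 0.2)           # value / L for an absent edge
  expect_equal(F[2, 3], 0)
  expect_equal(fuse_graphs(list(A1 * 0, A2 * 0)), matrix(0, 3, 3))
  expect_error(fuse_graphs(list(A1, matrix(0, 4, 4))), "mismatch")
})

test_that("spectral normalization matches the entrywise closed form", {
  # hand toys
  expect_equal(spectral_normalize(matrix(0, 3, 3)), diag(3))
  expect_equal(spectral_normalize(matrix(c(0, 1, 1, 0), 2)),
               matrix(0.5, 2, 2))
  A3 <- matrix(0, 3, 3); A3[1, 2] <- A3[2, 1] <- 1; A3[2, 3] <- A3[3, 2] <- 1
  Ah <- spectral_normalize(A3)
  expect_equal(Ah[1, 2], 1 / sqrt(6), tolerance = 1e-10)

  # brute-force double loop on random weighted graphs
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:7, 1)
    A <- matrix(runif(n * n), n, n); A <- (A + t(A)) / 2; diag(A) <- 0
    Ah <- spectral_normalize(A)
    expect_equal(Ah, oracle_conv(A), tolerance = 1e-12)
    expect_equal(Ah, t(Ah), tolerance = 1e-12)
    expect_true(all(Ah >= 0 & Ah <= 1) && all(diag(Ah) > 0))
  }
})

test_that("fused graph object is consistent and inductive extension is leak-free", {
  omics <- make_toy_omics(n = 15, p = c(6, 5), seed = 5)
  X <- lapply(omics, function(m) m$values)
  g <- build_fused_graph(X, K = 4)
  expect_equal(g$mu, c(0.3, 0.2))
  expect_equal(g$fused, fuse_graphs(g$per_omics))
  expect_equal(g$conv, spectral_normalize(g$fused))
  expect_true(all(diag(g$support)))

  # third layer defaults to mu = 0.3
  g3 <- build_fused_graph(make_toy_omics(n = 15, p = c(6, 5, 4), seed = 5),
                          K = 4)
  expect_equal(g3$mu, c(0.3, 0.2, 0.3))

  # inductive extension: training block unchanged, no test-test edges,
  # cross kernel uses the training delta_sq
  Xtr <- lapply(X, function(x) x[1:10, , drop = FALSE])
  Xte <- lapply(X, function(x) x[11:15, , drop = FALSE])
  gtr <- build_fused_graph(Xtr, K = 3)
  gall <- extend_graph(gtr, Xtr, Xte)
  expect_equal(gall$fused[1:10, 1:10], unclass(gtr$fused),
               ignore_attr = TRUE)
  expect_equal(gall$fused[11:15, 11:15], matrix(0, 5, 5),
               ignore_attr = TRUE)
  expect_equal(gall$delta_sq, gtr$delta_sq)
  # a test node's strongest cross edge reflects the training kernel
  d2 <- as.matrix(dist(rbind(Xte[[1]][1, ], Xtr[[1]])))[1, -1]^2
  nn <- order(d2)[1:3]
  w_expect <- exp(-d2[nn] / (0.3 * gtr$delta_sq[1]))
  expect_equal(unname(gall$per_omics[[1]][11, nn]), unname(w_expect),
               tolerance = 1e-12)
})
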