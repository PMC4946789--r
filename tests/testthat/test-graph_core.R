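test_that("kernel scale sigma is the maximum pairwise distance", {
  expect_equal(compute_sigma(matrix(c(0, 3, 4), ncol = 1)), 4)
  expect_equal(compute_sigma(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 5)
  expect_error(compute_sigma(matrix(1, 2, 3)), "degenerate")
})

test_that("Gaussian diffusion kernel evaluates and is symmetric", {
  expect_equal(gaussian_kernel(c(0, 0), c(0, 0), 2), 1)
  expect_equal(gaussian_kernel(0, 2, 4), exp(-1))
  set.seed(4)
  for (i in 1:20) {
    xi <- rnorm(3); xj <- rnorm(3); s <- runif(1, 0.5, 5)
    g <- gaussian_kernel(xi, xj, s)
    expect_equal(g, gaussian_kernel(xj, xi, s))
    expect_true(g > 0 && g <= 1)
  }
  expect_error(gaussian_kernel(c(1, NA), c(0, 0), 1), "non-finite")
})

test_that("kappa-NN sets exclude self, have size kappa, break ties by index", {
  g <- knn_sets(matrix(c(0, 3, 4), ncol = 1), 1)
  expect_equal(as.integer(g$neighbors), c(2L, 3L, 2L))
  # complete graph at kappa = N - 1
  X <- matrix(rnorm(12), 6, 2)
  g2 <- knn_sets(X, 5)
  for (i in 1:6) expect_setequal(g2$neighbors[i, ], setdiff(1:6, i))
  # equidistant tie at the kappa-th slot: lowest index retained
  Xt <- matrix(c(0, -1, 1, 5), ncol = 1)  # samples 2 and 3 equidistant from 1
  gt <- knn_sets(Xt, 1)
  expect_equal(gt$neighbors[1, ], 2L)
  expect_error(knn_sets(X, 6), "kappa")
  expect_error(knn_sets(X, 0), "kappa")
})

test_that("unsupervised affinity has kernel weights on edges, zero diagonal", {
  # farthest pair at distance sigma: W = e^{-sigma^2/sigma} = e^{-sigma}
  X <- matrix(c(0, 2), ncol = 1)
  g <- knn_sets(X, 1)
  W <- build_affinity_ge(X, g)
  expect_equal(W[1, 2], exp(-g$sigma))
  expect_equal(W[1, 2], W[2, 1])
  expect_equal(diag(W), c(0, 0))
  # pair outside each other's neighborhoods has zero affinity
  Xl <- matrix(c(0, 1, 10, 11), ncol = 1)
  Wl <- build_affinity_ge(Xl, knn_sets(Xl, 1))
  expect_equal(Wl[1, 3], 0)
  expect_identical(Wl, t(Wl))
})

test_that("affinity normalization follows the row-by-column-sum product rule", {
  W <- matrix(c(0, 2, 2, 0), 2)
  Wn <- normalize_affinity(W)
  expect_equal(Wn[1, 2], 0.5)
  W1 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(unclass(normalize_affinity(W1))[1:2, 1:2], W1)
  expect_error(normalize_affinity(matrix(c(0, 0, 1, 0), 2)), "isolated")
  # defining identity: Wn(i,j) * colsum_j(W) * rowsum_i(W) = W(i,j)
  set.seed(9)
  for (rep in 1:10) {
    W <- random_affinity(6, seed = rep)
    Wn <- normalize_affinity(W)
    back <- Wn * outer(rowSums(W), colSums(W))
    expect_equal(back, W, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("ncut normalization mode gives D^(-1/2) W D^(-1/2)", {
  W <- random_affinity(5, seed = 3)
  d <- rowSums(W)
  Wn <- normalize_affinity(W, mode = "ncut")
  expect_equal(unclass(Wn), diag(1 / sqrt(d)) %*% W %*% diag(1 / sqrt(d)),
               ignore_attr = TRUE)
})

test_that("two-node eigenproblem gives the hand-computed nontrivial pair", {
  Wn <- normalize_affinity(matrix(c(0, 2, 2, 0), 2))
  emb <- solve_embedding(Wn, 1)
  expect_equal(emb$eigenvalues, 2)
  expect_equal(emb$Y[1, 1], -emb$Y[2, 1])
  expect_gt(emb$Y[which.max(abs(emb$Y)), 1], 0)  # sign convention
})

test_that("embedding matches a dense generalized eigensolver on random graphs", {
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    k <- min(2L, n - 2L)
    Wn <- normalize_affinity(random_affinity(n, seed = 100 + rep))
    emb <- solve_embedding(Wn, k)
    orc <- oracle_generalized_eig(Wn, k)
    expect_equal(emb$eigenvalues, orc$values, tolerance = 1e-8)
    for (j in seq_len(k)) {
      expect_lt(max(abs(align_vec(emb$Y[, j]) - align_vec(orc$vectors[, j]))),
                1e-8)
    }
    # retained eigenvalues strictly positive and nondecreasing
    expect_true(all(emb$eigenvalues > 0))
    expect_true(!is.unsorted(emb$eigenvalues))
  }
})

test_that("disconnected graphs warn and shed all null vectors", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  Wn <- normalize_affinity(W)
  expect_warning(emb <- solve_embedding(Wn, 1), "disconnected")
  expect_gt(emb$eigenvalues[1], 1e-10)
})

test_that("graph_embedding is deterministic and shapes as requested", {
  sr <- make_swiss_roll(60, noise_sd = 0.02, seed = 8)
  e1 <- graph_embedding(sr$X, 6, 2)
  e2 <- graph_embedding(sr$X, 6, 2)
  expect_identical(e1$Y, e2$Y)
  expect_equal(ncol(graph_embedding(sr$X, 6, 1)$Y), 1L)
})

test_that("clean Swiss Roll embedding tracks the manifold parameter", {
  sr <- make_swiss_roll(600, noise_sd = 0, seed = 3)
  emb <- graph_embedding(sr$X, 10, 2)
  rc <- max(abs(stats::cor(emb$Y, sr$t, method = "spearman")))
  expect_gt(rc, 0.9)
})
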