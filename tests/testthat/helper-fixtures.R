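# Shared fixture builders and independent oracles, all generated in code.

# Random symmetric nonnegative affinity with zero diagonal, guaranteed
# connected via a spanning path.
random_affinity <- function(n, seed) {
  set.seed(seed)
  W <- matrix(runif(n * n, 0, 1), n, n)
  W[W < 0.35] <- 0           # some sparsity
  W <- pmax(W, t(W))
  diag(W) <- 0
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- runif(1, 0.5, 1)
  W
}

# Independent dense generalized eigensolve of (D - Wn) e = lambda D e via the
# non-symmetric route eigen(D^-1 L): different algorithm path from the
# package's symmetric reduction.
oracle_generalized_eig <- function(Wn, k, null_tol = 1e-10) {
  d <- rowSums(Wn)
  L <- diag(d) - Wn
  e <- eigen(diag(1 / d) %*% L)
  ord <- order(Re(e$values))
  lambda <- Re(e$values)[ord]
  V <- Re(e$vectors)[, ord, drop = FALSE]
  keep <- which(lambda > null_tol)[seq_len(k)]
  list(values = lambda[keep], vectors = V[, keep, drop = FALSE])
}

# Unit-normalize and sign-fix a vector (largest-magnitude entry positive).
align_vec <- function(v) {
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) -v else v
}

# Two well-separated Gaussian clusters in `d` dimensions.
two_clusters <- function(n_per = 25, d = 2, sep = 6, sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per * d, -sep / 2, sd), n_per, d),
    matrix(rnorm(n_per * d, sep / 2, sd), n_per, d))
  list(X = X, labels = rep(c(-1L, 1L), each = n_per))
}
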