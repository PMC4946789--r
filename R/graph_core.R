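# Unsupervised Graph Embedding: Gaussian diffusion kernel on a
# kappa-nearest-neighbour graph, normalized-cuts style affinity
# normalization, and the generalized eigenproblem (D - W~) e = lambda D e.

#' Kernel scale from the data diameter
#'
#' The Gaussian diffusion kernel scale sigma is fixed to the maximum pairwise
#' Euclidean distance of the dataset, so the kernel adapts to the global
#' spread of the features rather than requiring a tuned bandwidth.
#'
#' @param X numeric matrix, N samples x K features.
#' @return scalar sigma > 0 (distance units).
#' @examples
#' compute_sigma(matrix(c(0, 3, 4), ncol = 1))  # 4
#' @export
compute_sigma <- function(X) {
  X <- as_feature_matrix(X)
  sigma <- sqrt(max(pairwise_sqdist(X)))
  if (sigma <= 0) {
    stop("degenerate input: all samples identical (sigma = 0)")
  }
  sigma
}

#' Gaussian diffusion kernel
#'
#' Similarity gamma = exp(-||x_i - x_j||^2 / sigma), in (0, 1], equal to 1
#' only for identical points. Note the squared distance is scaled by sigma,
#' not sigma^2.
#'
#' @param xi,xj numeric feature vectors of equal length.
#' @param sigma positive kernel scale (see [compute_sigma()]).
#' @return scalar gamma in (0, 1].
#' @export
gaussian_kernel <- function(xi, xj, sigma) {
  if (!all(is.finite(xi)) || !all(is.finite(xj)) || !is.finite(sigma)) {
    stop("non-finite input to gaussian_kernel")
  }
  if (sigma <= 0) stop("sigma must be positive")
  if (length(xi) != length(xj)) stop("xi and xj must have equal length")
  exp(-sum((xi - xj)^2) / sigma)
}

#' kappa-nearest-neighbour sets
#'
#' For each sample, the kappa samples with smallest Euclidean distance
#' (self excluded). Distance ties are broken by lowest sample index so the
#' graph is reproducible.
#'
#' @param X numeric matrix, N x K.
#' @param kappa integer neighbour count, 2 <= kappa <= N - 1.
#' @param sigma kernel scale; computed from `X` when `NULL`.
#' @return object of class `neighbor_graph`: list with `kappa`, `sigma`,
#'   `neighbors` (N x kappa integer matrix, row i = K_i) and `n`.
#' @export
knn_sets <- function(X, kappa, sigma = NULL) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  kappa <- as.integer(kappa)
  if (kappa < 1L || kappa > n - 1L) {
    stop("kappa must satisfy 1 <= kappa <= N - 1 (N = ", n, ")")
  }
  if (is.null(sigma)) sigma <- compute_sigma(X)
  d2 <- pairwise_sqdist(X)
  nb <- matrix(0L, n, kappa)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    di[i] <- Inf
    ord <- order(di, seq_len(n))  # ties -> lowest index
    nb[i, ] <- ord[seq_len(kappa)]
  }
  structure(list(kappa = kappa, sigma = sigma, neighbors = nb, n = n),
            class = "neighbor_graph")
}

#' Unsupervised affinity matrix
#'
#' W(i, j) = gamma(x_i, x_j) when c_j is a kappa-nearest neighbour of c_i,
#' 0 otherwise. The directed kappa-NN relation is symmetrized by elementwise
#' maximum (union rule) so the downstream eigenproblem has a symmetric
#' operator; the diagonal is zero (no self-loops).
#'
#' @param X numeric matrix the graph was built from.
#' @param graph a `neighbor_graph` from [knn_sets()].
#' @return N x N symmetric affinity matrix with attribute `normalized = FALSE`.
#' @export
build_affinity_ge <- function(X, graph) {
  X <- as_feature_matrix(X)
  stopifnot(inherits(graph, "neighbor_graph"))
  if (graph$n != nrow(X)) stop("graph and X disagree on N")
  gam <- exp(-pairwise_sqdist(X) / graph$sigma)
  W <- matrix(0, graph$n, graph$n)
  for (i in seq_len(graph$n)) {
    W[i, graph$neighbors[i, ]] <- gam[i, graph$neighbors[i, ]]
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  attr(W, "normalized") <- FALSE
  W
}

#' Affinity normalization
#'
#' Default mode `"product"` divides each entry by the product of its row and
#' column sums, W~(i, j) = W(i, j) / (rowsum_i * colsum_j); for a symmetric W
#' this equals the degree-product scaling W / (d_i d_j). Mode `"ncut"` is the
#' standard normalized-cut symmetric scaling D^(-1/2) W D^(-1/2), provided
#' for comparison.
#'
#' @param W nonnegative affinity matrix with positive row/column sums.
#' @param mode `"product"` (default) or `"ncut"`.
#' @return normalized affinity matrix, attribute `normalized = TRUE`.
#' @export
normalize_affinity <- function(W, mode = c("product", "ncut")) {
  mode <- match.arg(mode)
  W <- as.matrix(W)
  rs <- rowSums(W)
  cs <- colSums(W)
  bad <- which(rs <= 0 | cs <= 0)
  if (length(bad) > 0) {
    stop("isolated vertex: sample(s) ", paste(bad, collapse = ", "),
         " have zero affinity row/column sum")
  }
  Wn <- if (mode == "product") {
    W / outer(rs, cs)
  } else {
    W / outer(sqrt(rs), sqrt(cs))
  }
  attr(Wn, "normalized") <- TRUE
  attr(Wn, "mode") <- mode
  Wn
}

#' Solve the graph-embedding eigenproblem
#'
#' Solves the generalized problem (D - W~) e = lambda D e, where D is the
#' diagonal degree matrix of the normalized affinity W~. Eigenvalues <= 1e-10
#' are treated as the graph's null space: the trivial constant eigenvector is
#' discarded (extra null vectors, indicating a disconnected graph, are
#' discarded with a warning) and the k eigenvectors of next-smallest
#' eigenvalue form the embedding columns, ordered by ascending eigenvalue.
#' Each eigenvector is sign-fixed so its largest-magnitude entry is positive.
#'
#' @param Wn normalized, symmetric affinity matrix.
#' @param k target dimensionality (k < N).
#' @return object of class `address_embedding`: list with `Y` (N x k),
#'   `eigenvalues` (length k, ascending), `eigenvectors` (same as columns of
#'   `Y`), `degree` (diagonal of D) and `k`.
#' @export
solve_embedding <- function(Wn, k) {
  Wn <- as.matrix(Wn)
  n <- nrow(Wn)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (n < k + 1L) stop("need N >= k + 1 samples for a k-dimensional embedding")
  if (max(abs(Wn - t(Wn))) > 1e-8 * max(abs(Wn))) {
    stop("normalized affinity must be symmetric")
  }
  d <- rowSums(Wn)
  if (any(d <= 0)) stop("degree matrix has non-positive entries")
  # Symmetric reduction: D^(-1/2) (D - W~) D^(-1/2) v = lambda v, e = D^(-1/2) v
  s <- 1 / sqrt(d)
  S <- (diag(n) - (s * Wn) * rep(s, each = n))
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  lambda <- rev(eig$values)
  V <- eig$vectors[, n:1, drop = FALSE]
  null_tol <- 1e-10
  null_idx <- which(lambda <= null_tol)
  if (length(null_idx) == 0L) null_idx <- 1L  # numerically lifted null vector
  if (length(null_idx) > 1L) {
    warning("graph appears disconnected: ", length(null_idx),
            " near-zero eigenvalues; all null vectors discarded")
  }
  keep <- setdiff(seq_len(n), null_idx)
  if (length(keep) < k) stop("fewer than k non-trivial eigenpairs available")
  keep <- keep[seq_len(k)]
  E <- s * V[, keep, drop = FALSE]
  # sign convention: largest-magnitude entry positive
  for (j in seq_len(k)) {
    m <- which.max(abs(E[, j]))
    if (E[m, j] < 0) E[, j] <- -E[, j]
  }
  colnames(E) <- paste0("y", seq_len(k))
  structure(list(Y = E, eigenvalues = lambda[keep], eigenvectors = E,
                 degree = d, k = k),
            class = "address_embedding")
}

#' Graph Embedding (GE)
#'
#' Full unsupervised pipeline: kernel scale from the data diameter, kappa-NN
#' graph, Gaussian affinities, normalization, generalized eigenproblem.
#' Deterministic for fixed input.
#'
#' @inheritParams knn_sets
#' @param k embedding dimensionality.
#' @param normalization passed to [normalize_affinity()].
#' @return an `address_embedding` (see [solve_embedding()]) with `sigma` and
#'   `kappa` recorded.
#' @export
graph_embedding <- function(X, kappa, k, normalization = "product") {
  X <- as_feature_matrix(X)
  g <- knn_sets(X, kappa)
  W <- build_affinity_ge(X, g)
  emb <- solve_embedding(normalize_affinity(W, normalization), k)
  emb$sigma <- g$sigma
  emb$kappa <- g$kappa
  emb$normalization <- normalization
  rownames(emb$Y) <- rownames(X)
  emb
}

#' @export
print.address_embedding <- function(x, ...) {
  cat(sprintf("graph embedding: %d samples x %d dimensions\n",
              nrow(x$Y), x$k))
  cat("retained eigenvalues:",
      paste(signif(x$eigenvalues, 6), collapse = ", "), "\n")
  invisible(x)
}
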