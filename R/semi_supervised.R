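# SSAGE: semi-supervised agglomerative graph embedding. Labelled neighbour
# pairs reweight the Gaussian kernel so same-class pairs attract
# (gamma * (1 + gamma)) and different-class pairs repel (gamma * (1 - gamma));
# pairs with an unlabelled member keep the plain kernel weight.

#' Label-aware SSAGE affinity matrix
#'
#' For each neighbour pair (c_j in K_i):
#' * both labelled, same class:      W^(i, j) = gamma (1 + gamma)
#' * both labelled, different class: W^(i, j) = gamma (1 - gamma)
#' * either member unlabelled:       W^(i, j) = gamma
#' and 0 for non-neighbours. The labelled branches fire only when BOTH
#' members carry a label; a pair of unlabelled samples is treated as the
#' plain unsupervised case, not as "same class 0". With every label 0 the
#' result equals the unsupervised affinity of [build_affinity_ge()] exactly.
#' Symmetrized by elementwise maximum as in the unsupervised case.
#'
#' @param X numeric matrix the graph was built from.
#' @param labels integer vector over \{+1, -1, 0\}; 0 = unlabelled.
#' @param graph a `neighbor_graph` from [knn_sets()].
#' @return N x N symmetric reweighted affinity matrix.
#' @export
build_affinity_ssage <- function(X, labels, graph) {
  X <- as_feature_matrix(X)
  stopifnot(inherits(graph, "neighbor_graph"))
  if (graph$n != nrow(X)) stop("graph and X disagree on N")
  labels <- check_labels(labels, nrow(X))
  gam <- exp(-pairwise_sqdist(X) / graph$sigma)
  both <- outer(labels != 0L, labels != 0L, "&")
  same <- outer(labels, labels, "==") & both
  diff <- outer(labels, labels, "!=") & both
  mult <- matrix(1, graph$n, graph$n)
  mult[same] <- 1 + gam[same]
  mult[diff] <- 1 - gam[diff]
  A <- gam * mult
  W <- matrix(0, graph$n, graph$n)
  for (i in seq_len(graph$n)) {
    W[i, graph$neighbors[i, ]] <- A[i, graph$neighbors[i, ]]
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  attr(W, "normalized") <- FALSE
  W
}

#' SSAGE embedding
#'
#' Semi-supervised embedding: label-reweighted affinity, then the same
#' normalization and generalized eigenproblem as [graph_embedding()].
#' Deterministic for fixed input and labels; with an empty label set it
#' reduces exactly to the unsupervised embedding.
#'
#' @inheritParams build_affinity_ssage
#' @param kappa neighbour count.
#' @param k embedding dimensionality.
#' @param normalization passed to [normalize_affinity()].
#' @return an `address_embedding`.
#' @export
ssage_embed <- function(X, labels, kappa, k, normalization = "product") {
  X <- as_feature_matrix(X)
  g <- knn_sets(X, kappa)
  W <- build_affinity_ssage(X, labels, g)
  emb <- solve_embedding(normalize_affinity(W, normalization), k)
  emb$sigma <- g$sigma
  emb$kappa <- g$kappa
  emb$normalization <- normalization
  rownames(emb$Y) <- rownames(X)
  emb
}
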