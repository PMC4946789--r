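# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
as_feature_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("feature matrix needs at least 2 samples")
  if (ncol(X) < 1L) stop("feature matrix needs at least 1 feature")
  if (!all(is.finite(X))) stop("feature matrix contains non-finite entries")
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  X
}

#' @keywords internal
#' @noRd
check_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("label vector length ", length(labels), " does not match N = ", n)
  }
  if (!all(labels %in% c(-1L, 0L, 1L))) {
    stop("labels must take values in {+1, -1, 0} (0 = unlabeled)")
  }
  labels
}

# Squared Euclidean pairwise distances; exact zero diagonal.
#' @keywords internal
#' @noRd
pairwise_sqdist <- function(X) {
  d <- as.matrix(stats::dist(X))^2
  diag(d) <- 0
  d
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package randomness never leaks.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-run child seeds below 2^31 derived from a master seed.
#' @keywords internal
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
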