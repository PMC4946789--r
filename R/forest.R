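# Evaluation classifier: bagged ensemble of 50 CART-style decision trees
# (Gini impurity, axis-aligned splits), each tree trained on a seeded random
# third of the training pool, prediction by consensus vote. Used only to
# score embeddings, never inside the active-learning loop (which uses the
# SVM), so the two classifiers stay independent.

# Grow one binary classification tree; y in {-1, +1}. Returns a nested list.
#' @keywords internal
#' @noRd
grow_tree <- function(X, y, depth = 0L, max_depth = 15L, min_n = 2L) {
  n <- length(y)
  n_pos <- sum(y > 0)
  # leaf vote: majority, ties to +1
  vote <- if (n_pos * 2L >= n) 1L else -1L
  if (depth >= max_depth || n < min_n || n_pos == 0L || n_pos == n) {
    return(list(leaf = TRUE, vote = vote))
  }
  best <- NULL
  best_gini <- Inf
  for (f in seq_len(ncol(X))) {
    xo <- order(X[, f])
    xs <- X[xo, f]
    ys <- y[xo] > 0
    cum_pos <- cumsum(ys)
    # candidate split after position i (xs[i] < xs[i+1])
    i <- seq_len(n - 1L)
    valid <- xs[i] < xs[i + 1L]
    if (!any(valid)) next
    nl <- i
    pl <- cum_pos[i]
    nr <- n - nl
    pr <- n_pos - pl
    gini <- nl * (1 - (pl / nl)^2 - ((nl - pl) / nl)^2) +
            nr * (1 - (pr / nr)^2 - ((nr - pr) / nr)^2)
    gini[!valid] <- Inf
    j <- which.min(gini)
    if (gini[j] < best_gini) {
      best_gini <- gini[j]
      best <- list(feature = f, threshold = (xs[j] + xs[j + 1L]) / 2)
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, vote = vote))
  go_left <- X[, best$feature] <= best$threshold
  if (all(go_left) || !any(go_left)) return(list(leaf = TRUE, vote = vote))
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(X[go_left, , drop = FALSE], y[go_left],
                        depth + 1L, max_depth, min_n),
       right = grow_tree(X[!go_left, , drop = FALSE], y[!go_left],
                         depth + 1L, max_depth, min_n))
}

#' @keywords internal
#' @noRd
predict_tree <- function(tree, X) {
  out <- integer(nrow(X))
  rec <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) {
      out[idx] <<- node$vote
      return()
    }
    left <- X[idx, node$feature] <= node$threshold
    rec(node$left, idx[left])
    rec(node$right, idx[!left])
  }
  rec(tree, seq_len(nrow(X)))
  out
}

#' Random-forest accuracy of an embedding
#'
#' Scores class separability of embedding coordinates with a bagged ensemble
#' of `n_trees` decision trees, each trained on a seeded random third of the
#' training pool, predicting the held-out test pool by consensus vote (vote
#' ties go to +1). Seeded and fully deterministic.
#'
#' @param Y embedding coordinate matrix over all samples (or an
#'   `address_embedding`).
#' @param train_idx,train_labels training-pool indices and their +1/-1 labels.
#' @param test_idx,test_labels held-out test-pool indices and labels.
#' @param seed integer seed for the bagging draws.
#' @param n_trees ensemble size (default 50).
#' @return scalar accuracy in \[0, 1\].
#' @export
random_forest_accuracy <- function(Y, train_idx, train_labels,
                                   test_idx, test_labels,
                                   seed = 1L, n_trees = 50L) {
  if (inherits(Y, "address_embedding")) Y <- Y$Y
  Y <- as.matrix(Y)
  train_idx <- as.integer(train_idx)
  test_idx <- as.integer(test_idx)
  y_tr <- as.integer(train_labels)
  y_ts <- as.integer(test_labels)
  if (length(train_idx) == 0L || length(test_idx) == 0L) {
    stop("training and test pools must be nonempty")
  }
  if (!all(c(y_tr, y_ts) %in% c(-1L, 1L))) stop("labels must be +1/-1")
  if (length(unique(y_tr)) < 2L) stop("training pool must contain both classes")
  Xtr <- Y[train_idx, , drop = FALSE]
  Xts <- Y[test_idx, , drop = FALSE]
  m <- max(2L, floor(length(train_idx) / 3))
  votes <- matrix(0L, length(test_idx), n_trees)
  bags <- with_seed(seed, {
    lapply(seq_len(n_trees), function(t) sample.int(length(train_idx), m))
  })
  for (t in seq_len(n_trees)) {
    bag <- bags[[t]]
    if (length(unique(y_tr[bag])) < 2L) {
      votes[, t] <- y_tr[bag][1]  # single-class bag votes its class
    } else {
      tree <- grow_tree(Xtr[bag, , drop = FALSE], y_tr[bag])
      votes[, t] <- predict_tree(tree, Xts)
    }
  }
  pred <- ifelse(rowSums(votes) >= 0, 1L, -1L)
  cc <- confusion_counts(y_ts, pred)
  accuracy(cc$TP, cc$TN, cc$FP, cc$FN)
}
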