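# Probabilistic linear SVM used by the uncertainty-sampling active learner.
# Soft-margin dual solved with quadprog; posteriors via Platt's sigmoid fit
# on the decision values; cost selected by seeded, stratified cross-validated
# grid search (linear kernel, so only the cost parameter is searched).

#' Classifier configuration
#'
#' @param cost_grid candidate soft-margin cost values; default 2^-5..2^15 in
#'   multiplicative steps of 4, the standard coarse grid-search ladder.
#' @param kernel_width_grid candidate RBF widths; parsed for config fidelity
#'   but ignored under the fixed linear kernel (a notice is emitted once).
#' @param cv_folds folds for the cost search (stratified); reduced
#'   automatically when a class has fewer members than folds.
#' @param calibration logical; fit Platt's sigmoid for posterior output.
#' @param seed integer seed for the fold assignment.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(cost_grid = 2^seq(-5, 15, by = 2),
                              kernel_width_grid = NULL,
                              cv_folds = 5L, calibration = TRUE,
                              seed = 1L) {
  if (length(cost_grid) == 0) stop("cost_grid must be nonempty")
  if (!is.null(kernel_width_grid)) {
    message("linear kernel in use: kernel_width_grid is ignored")
  }
  structure(list(kernel = "linear", cost_grid = sort(cost_grid),
                 kernel_width_grid = kernel_width_grid,
                 cv_folds = as.integer(cv_folds),
                 calibration = isTRUE(calibration),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# Soft-margin linear SVM via the quadprog dual. y in {-1, +1}.
#' @keywords internal
#' @noRd
svm_linear_fit <- function(X, y, cost) {
  X <- as.matrix(X)
  n <- nrow(X)
  # normalize the coordinate scale so the QP is well conditioned across the
  # cost grid; w is mapped back afterwards (decision values are unchanged)
  sc <- sqrt(mean(X^2))
  if (sc <= 0) sc <- 1
  Xs <- X / sc
  K <- tcrossprod(Xs)
  Q0 <- (y %o% y) * K
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-cost, n))
  sol <- NULL
  for (ridge in c(1e-8, 1e-6, 1e-4, 1e-2)) {
    Q <- Q0
    diag(Q) <- diag(Q) + ridge * max(1, mean(diag(K)))
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = Q, dvec = rep(1, n),
                         Amat = Amat, bvec = bvec, meq = 1),
      error = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol)) stop("SVM quadratic program failed to solve")
  alpha <- pmin(pmax(sol$solution, 0), cost)
  ws <- colSums(alpha * y * Xs)
  margin <- which(alpha > 1e-6 * cost & alpha < cost * (1 - 1e-6))
  sv <- if (length(margin) > 0) margin else which(alpha > 1e-6 * cost)
  b <- if (length(sv) > 0) mean(y[sv] - Xs[sv, , drop = FALSE] %*% ws) else 0
  list(w = ws / sc, b = as.numeric(b), cost = cost)
}

#' @keywords internal
#' @noRd
svm_decision <- function(model, X) {
  as.numeric(as.matrix(X) %*% model$w + model$b)
}

# Platt (1999) sigmoid fit with regularized targets; deterministic.
#' @keywords internal
#' @noRd
platt_fit <- function(f, y) {
  np <- sum(y > 0)
  nn <- sum(y < 0)
  t <- ifelse(y > 0, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    # numerically stable -sum(t*log(p) + (1-t)*log(1-p)), p = 1/(1+e^z)
    sum(pmax(z, 0) + log1p(exp(-abs(z))) - (1 - t) * z)
  }
  fit <- stats::optim(c(-1, 0), nll, method = "BFGS")
  list(A = fit$par[1], B = fit$par[2])
}

#' @keywords internal
#' @noRd
platt_prob <- function(platt, f) {
  1 / (1 + exp(platt$A * f + platt$B))
}

# Stratified fold ids; every fold keeps both classes where possible.
#' @keywords internal
#' @noRd
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Train the probabilistic linear SVM
#'
#' Maximum-margin linear classifier with calibrated posterior output,
#' used as the active learner over embedding coordinates. The cost parameter
#' is chosen by seeded stratified cross-validated grid search (accuracy;
#' ties go to the cost nearest the neutral default 1). When the training set
#' is too small for
#' cross-validation (a class with a single member), the median grid cost is
#' used. Posteriors are P(label = +1) from a Platt sigmoid on the decision
#' values (falls back to a fixed-slope sigmoid when the training decision
#' values are perfectly separated at a single point).
#'
#' @param Y numeric matrix of embedding coordinates (training rows).
#' @param labels vector over \{+1, -1\} for those rows.
#' @param config a [classifier_config()].
#' @return object of class `svm_posterior_model`.
#' @export
train_probabilistic_classifier <- function(Y, labels, config = classifier_config()) {
  Y <- as.matrix(Y)
  y <- as.integer(labels)
  if (!all(y %in% c(-1L, 1L))) stop("training labels must be +1/-1")
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; enlarge the initial label set")
  }
  if (nrow(Y) != length(y)) stop("Y rows and labels disagree")
  grid <- config$cost_grid
  nmin <- min(table(y))
  folds <- min(config$cv_folds, nmin)
  cost <- if (folds >= 2L && length(grid) > 1L) {
    fold <- stratified_folds(y, folds, config$seed)
    cv_acc <- vapply(grid, function(C) {
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L) next
        m <- svm_linear_fit(Y[tr, , drop = FALSE], y[tr], C)
        pred <- ifelse(svm_decision(m, Y[!tr, , drop = FALSE]) >= 0, 1L, -1L)
        correct <- correct + sum(pred == y[!tr])
      }
      correct / length(y)
    }, numeric(1))
    # among equally accurate costs prefer the one nearest the neutral C = 1
    best <- which(cv_acc == max(cv_acc))
    grid[best[which.min(abs(log(grid[best])))]]
  } else {
    grid[ceiling(length(grid) / 2)]
  }
  model <- svm_linear_fit(Y, y, cost)
  f <- svm_decision(model, Y)
  platt <- if (config$calibration && stats::sd(f) > 1e-12) {
    platt_fit(f, y)
  } else {
    list(A = -1, B = 0)
  }
  structure(list(svm = model, platt = platt, cost = cost, config = config),
            class = "svm_posterior_model")
}

#' Posterior class probabilities
#'
#' @param model an `svm_posterior_model`.
#' @param Y matrix of embedding coordinates to score.
#' @return numeric vector of P(label = +1), each in \[0, 1\].
#' @export
predict_posterior <- function(model, Y) {
  stopifnot(inherits(model, "svm_posterior_model"))
  p <- platt_prob(model$platt, svm_decision(model$svm, as.matrix(Y)))
  pmin(pmax(p, 0), 1)
}
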