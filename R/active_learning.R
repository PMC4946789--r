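# Uncertainty sampling and the iterative AdDReSS loop: embed, train the
# probabilistic SVM on the labelled set, query the pool samples whose
# posterior is nearest 0.5, reveal their labels, re-embed with SSAGE.

#' Active-learning state
#'
#' @param S_tr integer indices of the labelled training set.
#' @param S_ts integer indices of the unlabelled query pool.
#' @return list of class `al_state` with `S_tr`, `S_ts`, `S_a` (last query
#'   set) and `history` (one record per iteration).
#' @export
al_state <- function(S_tr, S_ts) {
  S_tr <- as.integer(S_tr)
  S_ts <- as.integer(S_ts)
  if (length(intersect(S_tr, S_ts)) > 0) stop("S_tr and S_ts must be disjoint")
  structure(list(S_tr = S_tr, S_ts = S_ts, S_a = integer(0),
                 history = list()),
            class = "al_state")
}

#' Oracle from a ground-truth label vector
#'
#' Wraps a hidden truth vector as the callable the active learner queries.
#'
#' @param truth integer vector over \{+1, -1\} for every sample.
#' @return function(indices) -> labels in \{+1, -1\}.
#' @export
make_oracle <- function(truth) {
  truth <- as.integer(truth)
  if (!all(truth %in% c(-1L, 1L))) stop("oracle truth must be +1/-1")
  function(idx) truth[as.integer(idx)]
}

#' Select ambiguous samples
#'
#' The min(b, pool size) pool samples minimizing |P(label = +1) - 0.5|,
#' ties broken by lowest sample index.
#'
#' @param posterior numeric vector of P(label = +1) aligned with `pool`.
#' @param pool integer indices the posteriors refer to.
#' @param b batch size, >= 1.
#' @return integer vector of queried sample indices (subset of `pool`).
#' @export
select_ambiguous <- function(posterior, pool, b) {
  pool <- as.integer(pool)
  if (length(pool) == 0) stop("query pool is empty")
  if (length(posterior) != length(pool)) stop("posterior and pool disagree")
  b <- as.integer(b)
  if (b < 1L) stop("batch size b must be >= 1")
  ord <- order(abs(posterior - 0.5), pool)
  pool[ord[seq_len(min(b, length(pool)))]]
}

#' Move queried samples into the training set
#'
#' @param state an `al_state`.
#' @param S_a queried indices, a subset of `state$S_ts`.
#' @param labels oracle labels (+1/-1) for `S_a`.
#' @return updated `al_state`; pool conservation and disjointness preserved.
#' @export
update_training <- function(state, S_a, labels) {
  stopifnot(inherits(state, "al_state"))
  S_a <- as.integer(S_a)
  if (!all(S_a %in% state$S_ts)) stop("queried set S_a is not a subset of the pool S_ts")
  if (length(labels) != length(S_a) || !all(labels %in% c(-1L, 1L))) {
    stop("oracle must supply a +1/-1 label for each queried sample")
  }
  state$S_tr <- c(state$S_tr, S_a)
  state$S_ts <- setdiff(state$S_ts, S_a)
  state$S_a <- S_a
  state
}

# Shared loop body for AdDReSS and the random-sampling comparator.
#' @keywords internal
#' @noRd
al_loop <- function(X, labels, oracle, kappa, k, b, max_queries,
                    pool, config, normalization, sampler) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  labels <- check_labels(labels, n)
  S_tr <- which(labels != 0L)
  if (is.null(pool)) pool <- setdiff(which(labels == 0L), integer(0))
  pool <- setdiff(as.integer(pool), S_tr)
  state <- al_state(S_tr, pool)
  # line 0: initial embedding is the unsupervised one (no labels used)
  emb <- graph_embedding(X, kappa, k, normalization)
  queried_total <- 0L
  it <- 0L
  while (length(state$S_ts) > 0 && queried_total < max_queries) {
    it <- it + 1L
    if (length(unique(labels[state$S_tr])) < 2L) {
      stop("labelled set contains a single class; enlarge the initial label set")
    }
    bi <- min(b, length(state$S_ts), max_queries - queried_total)
    S_a <- sampler(emb, labels, state, bi)
    new_labels <- oracle(S_a)
    state <- update_training(state, S_a, new_labels)
    labels[S_a] <- as.integer(new_labels)
    emb <- ssage_embed(X, labels, kappa, k, normalization)
    queried_total <- queried_total + length(S_a)
    state$history[[it]] <- list(iteration = it, queried = S_a,
                                n_labeled = length(state$S_tr),
                                eigenvalues = emb$eigenvalues)
  }
  list(embedding = emb, state = state, labels = labels,
       n_queries = queried_total)
}

#' AdDReSS: adaptive dimensionality reduction with semi-supervision
#'
#' Iterative scheme: (0) build the unsupervised embedding; then, while the
#' pool is nonempty and the query budget remains, (1) train the probabilistic
#' linear SVM on the labelled embedding rows, (2) predict posteriors over the
#' pool, (3) query the batch of most ambiguous samples (posterior nearest
#' 0.5), (4) reveal their labels through the oracle, and (5) re-embed with
#' SSAGE using the enlarged label set. The pool shrinks every iteration, so
#' termination is guaranteed.
#'
#' @param X numeric feature matrix, N x K.
#' @param labels initial labels over \{+1, -1, 0\}; the nonzero entries form
#'   S_tr and must contain both classes.
#' @param oracle callable `function(indices) -> +1/-1`, e.g. [make_oracle()].
#' @param kappa,k graph and embedding parameters.
#' @param b query batch size per iteration.
#' @param max_queries total query budget (default unlimited).
#' @param pool indices eligible for querying (default: all unlabelled
#'   samples). Samples outside `pool` are embedded but never queried.
#' @param config a [classifier_config()].
#' @param normalization affinity normalization mode.
#' @return list: `embedding` (final `address_embedding`), `state` (an
#'   `al_state` with per-iteration history), `labels` (final label vector),
#'   `n_queries`.
#' @export
address <- function(X, labels, oracle, kappa, k, b = 5L, max_queries = Inf,
                    pool = NULL, config = classifier_config(),
                    normalization = "product") {
  sampler <- function(emb, labs, state, bi) {
    model <- train_probabilistic_classifier(
      emb$Y[state$S_tr, , drop = FALSE], labs[state$S_tr], config)
    post <- predict_posterior(model, emb$Y[state$S_ts, , drop = FALSE])
    select_ambiguous(post, state$S_ts, bi)
  }
  al_loop(X, labels, oracle, kappa, k, b, max_queries, pool, config,
          normalization, sampler)
}

#' Random-sampling comparator (SSAGE baseline)
#'
#' Identical loop to [address()] but the query batch is drawn uniformly at
#' random (seeded) from the pool, giving the label-reveal trajectory of
#' SSAGE under random sampling. With the pool exhausted both strategies hold
#' the same label set and produce identical final embeddings.
#'
#' @inheritParams address
#' @param seed integer seed driving the random query draws.
#' @return as [address()].
#' @export
random_sampling_baseline <- function(X, labels, oracle, kappa, k, b = 5L,
                                     max_queries = Inf, pool = NULL,
                                     seed = 1L, config = classifier_config(),
                                     normalization = "product") {
  seeds_env <- new.env()
  seeds_env$i <- 0L
  sampler <- function(emb, labs, state, bi) {
    seeds_env$i <- seeds_env$i + 1L
    with_seed(seed + seeds_env$i, {
      state$S_ts[sample.int(length(state$S_ts), bi)]
    })
  }
  al_loop(X, labels, oracle, kappa, k, b, max_queries, pool, config,
          normalization, sampler)
}
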