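# Experiment harness: stratified train/test pools, label-reveal schedules
# from 10% to 50% of the dataset, repeated seeded runs, and the learning-
# curve comparison of GE, SSAGE (random sampling) and AdDReSS.

#' Stratified train/test pool split
#'
#' Splits samples into disjoint pools E_tr and E_ts with equal per-class
#' counts (for odd class counts the extra sample goes to E_tr). Embeddings
#' and label queries use only E_tr labels; E_ts labels are reserved for
#' evaluation.
#'
#' @param truth full +1/-1 label vector.
#' @param fraction proportion assigned to E_tr (default 0.5, equal pools).
#' @param seed integer seed.
#' @return list with integer index vectors `E_tr` and `E_ts`.
#' @export
stratified_split <- function(truth, fraction = 0.5, seed = 1L) {
  truth <- as.integer(truth)
  if (!all(truth %in% c(-1L, 1L))) stop("truth labels must be +1/-1")
  if (min(table(truth)) < 2L) stop("each class needs at least 2 members")
  E_tr <- integer(0)
  with_seed(seed, {
    for (cls in c(1L, -1L)) {
      idx <- which(truth == cls)
      n_tr <- ceiling(length(idx) * fraction)
      E_tr <- c(E_tr, sample(idx)[seq_len(n_tr)])
    }
  })
  E_tr <- sort(E_tr)
  list(E_tr = E_tr, E_ts = setdiff(seq_along(truth), E_tr))
}

# Stratified initial labelled set of size m drawn from pool E_tr.
#' @keywords internal
#' @noRd
initial_training_set <- function(truth, E_tr, m, seed) {
  with_seed(seed, {
    pos <- sample(E_tr[truth[E_tr] == 1L])
    neg <- sample(E_tr[truth[E_tr] == -1L])
    m_pos <- max(1L, min(length(pos), round(m * length(pos) / length(E_tr))))
    m_neg <- max(1L, min(length(neg), m - m_pos))
    sort(c(pos[seq_len(m_pos)], neg[seq_len(m_neg)]))
  })
}

# One label-reveal trajectory (SSAGE or AdDReSS) over the n_labels grid.
# Returns per-grid-point acc/si. Labels outside E_tr are never revealed.
#' @keywords internal
#' @noRd
run_reveal_schedule <- function(X, truth, split, n_grid, method, kappa, k, b,
                                seeds, config, normalization, rf_trees,
                                init_S_tr) {
  E_tr <- split$E_tr
  E_ts <- split$E_ts
  n_pts <- length(n_grid)
  labels <- integer(nrow(X))
  labels[init_S_tr] <- truth[init_S_tr]
  pool <- setdiff(E_tr, init_S_tr)
  emb <- ssage_embed(X, labels, kappa, k, normalization)
  acc <- si <- numeric(n_pts)
  rand_it <- 0L
  record <- function(j) {
    acc[j] <<- random_forest_accuracy(emb, E_tr, truth[E_tr], E_ts,
                                      truth[E_ts], seed = seeds["rf"],
                                      n_trees = rf_trees)
    si[j] <<- silhouette_index(emb$Y[E_tr, , drop = FALSE], truth[E_tr])
  }
  record(1L)
  for (j in seq_len(n_pts)[-1]) {
    target <- min(n_grid[j], length(E_tr))
    while (sum(labels != 0L) < target && length(pool) > 0L) {
      inc <- target - sum(labels != 0L)
      bi <- min(if (is.null(b)) inc else b, inc, length(pool))
      S_a <- if (method == "AdDReSS") {
        model <- train_probabilistic_classifier(
          emb$Y[labels != 0L, , drop = FALSE], labels[labels != 0L], config)
        post <- predict_posterior(model, emb$Y[pool, , drop = FALSE])
        select_ambiguous(post, pool, bi)
      } else {
        rand_it <<- rand_it + 1L
        with_seed(seeds["query"] + rand_it, pool[sample.int(length(pool), bi)])
      }
      stopifnot(all(S_a %in% E_tr))  # E_ts labels are never revealed
      labels[S_a] <- truth[S_a]
      pool <- setdiff(pool, S_a)
      emb <- ssage_embed(X, labels, kappa, k, normalization)
    }
    record(j)
  }
  data.frame(n_labels = pmin(n_grid, length(E_tr)), acc = acc, si = si)
}

#' Label-reveal learning curves for GE, SSAGE and AdDReSS
#'
#' Runs the full comparison protocol: for each of `n_runs` seeded runs the
#' data are split into stratified half pools E_tr/E_ts, an initial stratified
#' labelled set at the lowest label fraction is drawn (identical for SSAGE
#' and AdDReSS within a run), and the reveal schedule advances across
#' `label_fractions` — AdDReSS queries by uncertainty sampling, SSAGE
#' uniformly at random, GE ignores labels (one embedding for all fractions).
#' At every grid point the embedding is scored by random-forest accuracy on
#' E_ts and Silhouette Index on E_tr. Fully determined by `seed`.
#'
#' @param X feature matrix, N x K.
#' @param truth full +1/-1 label vector (hidden ground truth; only E_tr
#'   entries are ever revealed to the learners).
#' @param methods subset of `c("GE", "SSAGE", "AdDReSS")`.
#' @param label_fractions ascending reveal grid, as fractions of N.
#' @param n_runs number of random initializations (paper-style default 20).
#' @param kappa,k graph and embedding parameters.
#' @param b active-learning batch size; `NULL` (default) aligns the batch
#'   with the label-reveal increment (one iteration per grid step).
#' @param seed master seed; per-run seeds are derived deterministically.
#' @param config a [classifier_config()].
#' @param normalization affinity normalization mode.
#' @param rf_trees evaluation forest size.
#' @return object of class `learning_curves`: data.frame with columns
#'   method, run, label_fraction, n_labels, acc, si.
#' @export
run_learning_curves <- function(X, truth,
                                methods = c("GE", "SSAGE", "AdDReSS"),
                                label_fractions = seq(0.1, 0.5, by = 0.1),
                                n_runs = 20L, kappa = 10L, k = 2L, b = NULL,
                                seed = 1L, config = classifier_config(),
                                normalization = "product", rf_trees = 50L) {
  X <- as_feature_matrix(X)
  truth <- as.integer(truth)
  methods <- match.arg(methods, c("GE", "SSAGE", "AdDReSS"), several.ok = TRUE)
  if (is.unsorted(label_fractions, strictly = TRUE)) {
    stop("label_fractions must be strictly ascending")
  }
  n <- nrow(X)
  n_grid <- pmax(2L, round(label_fractions * n))
  run_seeds <- derive_seeds(seed, n_runs)
  # GE ignores labels: one embedding serves every run and fraction
  ge_emb <- if ("GE" %in% methods) graph_embedding(X, kappa, k, normalization)
  out <- list()
  for (r in seq_len(n_runs)) {
    comp <- derive_seeds(run_seeds[r], 4)
    seeds <- c(split = comp[1], init = comp[2], rf = comp[3], query = comp[4])
    split <- stratified_split(truth, 0.5, seeds["split"])
    init_S_tr <- initial_training_set(truth, split$E_tr, n_grid[1],
                                      seeds["init"])
    for (m in methods) {
      res <- if (m == "GE") {
        emb <- ge_emb
        a <- random_forest_accuracy(emb, split$E_tr, truth[split$E_tr],
                                    split$E_ts, truth[split$E_ts],
                                    seed = seeds["rf"], n_trees = rf_trees)
        s <- silhouette_index(emb$Y[split$E_tr, , drop = FALSE],
                              truth[split$E_tr])
        data.frame(n_labels = pmin(n_grid, length(split$E_tr)),
                   acc = a, si = s)
      } else {
        run_reveal_schedule(X, truth, split, n_grid, m, kappa, k, b,
                            seeds, config, normalization, rf_trees,
                            init_S_tr)
      }
      out[[length(out) + 1L]] <- data.frame(
        method = m, run = r, label_fraction = label_fractions,
        res, row.names = NULL)
    }
  }
  curves <- do.call(rbind, out)
  class(curves) <- c("learning_curves", "data.frame")
  attr(curves, "n_total") <- n
  curves
}

#' Efficiency and variance report from learning curves
#'
#' Aggregates per-method mean and sd curves, per-fraction score variances
#' (rho_Acc, rho_SI), the empirical maximum accuracy, and — when both
#' methods of a pair are present — Raghavan efficiencies for
#' (AdDReSS | GE), (SSAGE | GE) and (AdDReSS | SSAGE), maximum query
#' efficiency and maximum information gain for (AdDReSS, SSAGE), and the
#' percentage efficiency improvement of AdDReSS over SSAGE against the GE
#' baseline. Pairwise efficiencies use the empirical-maximum reference
#' level, since the flat GE baseline makes the final-random reference
#' degenerate.
#'
#' @param curves a `learning_curves` data.frame (or compatible).
#' @param n_total total sample count N; defaults to the attribute recorded
#'   by [run_learning_curves()].
#' @return list of class `efficiency_report` with elements `mean_curves`,
#'   `variances`, `empirical_max`, `efficiency`, `mqe`, `mig`, `delta_eff`.
#' @export
efficiency_report <- function(curves, n_total = attr(curves, "n_total")) {
  if (is.null(n_total)) stop("supply n_total (total sample count)")
  curves <- as.data.frame(curves)
  needed <- c("method", "run", "label_fraction", "n_labels", "acc", "si")
  if (!all(needed %in% names(curves))) {
    stop("curves must have columns ", paste(needed, collapse = ", "))
  }
  agg <- function(v) {
    stats::aggregate(cbind(acc, si) ~ method + label_fraction + n_labels,
                     data = curves, FUN = v)
  }
  mc <- agg(mean)
  sdc <- agg(stats::sd)
  names(sdc)[names(sdc) %in% c("acc", "si")] <- c("acc_sd", "si_sd")
  mean_curves <- merge(mc, sdc,
                       by = c("method", "label_fraction", "n_labels"))
  mean_curves <- mean_curves[order(mean_curves$method,
                                   mean_curves$label_fraction), ]
  n_runs <- max(curves$run)
  variances <- if (n_runs >= 2L) {
    v <- stats::aggregate(cbind(acc, si) ~ method + label_fraction + n_labels,
                          data = curves, FUN = score_variance)
    names(v)[names(v) %in% c("acc", "si")] <- c("rho_acc", "rho_si")
    v[order(v$method, v$label_fraction), ]
  } else {
    NULL
  }
  em <- empirical_max(curves$acc)
  meth <- unique(curves$method)
  curve_of <- function(m) {
    sub <- mean_curves[mean_curves$method == m, ]
    sub[order(sub$n_labels), ]
  }
  eff <- list()
  pairs <- list(c("AdDReSS", "GE"), c("SSAGE", "GE"), c("AdDReSS", "SSAGE"))
  for (p in pairs) {
    if (all(p %in% meth)) {
      eff[[paste(p, collapse = "|")]] <- raghavan_efficiency(
        curve_of(p[1])$acc, curve_of(p[2])$acc,
        reference = "empirical_max", empirical_max = em)
    }
  }
  mqe <- mig <- delta <- NULL
  if (all(c("AdDReSS", "SSAGE") %in% meth)) {
    ad <- curve_of("AdDReSS")
    ss <- curve_of("SSAGE")
    mqe <- max_query_efficiency(ad$acc, ss$acc, ad$n_labels, n_total)
    mig <- max_information_gain(ad$acc, ss$acc)
  }
  if (all(c("AdDReSS|GE", "SSAGE|GE") %in% names(eff))) {
    delta <- efficiency_improvement(eff[["AdDReSS|GE"]], eff[["SSAGE|GE"]])
  }
  structure(list(mean_curves = mean_curves, variances = variances,
                 empirical_max = em, efficiency = eff, mqe = mqe, mig = mig,
                 delta_eff = delta, n_total = n_total),
            class = "efficiency_report")
}

#' Write curves and report files
#'
#' `write_curves()` writes the long-format curves CSV (deterministic, so
#' identical configurations reproduce it byte-for-byte);
#' `write_report()` writes `report.json` (all efficiency measures) and
#' `mean_curves.csv` (plot-ready long format).
#'
#' @param curves a `learning_curves` data.frame.
#' @param path output CSV path.
#' @return the input, invisibly.
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(curves)
}

#' @rdname write_curves
#' @param report an `efficiency_report`.
#' @param dir output directory for `report.json` and `mean_curves.csv`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "efficiency_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$mean_curves, file.path(dir, "mean_curves.csv"),
                   row.names = FALSE)
  if (!is.null(report$variances)) {
    utils::write.csv(report$variances, file.path(dir, "variances.csv"),
                     row.names = FALSE)
  }
  json <- list(empirical_max = report$empirical_max,
               efficiency = report$efficiency,
               mqe = report$mqe, mig = report$mig,
               delta_eff_percent = as.numeric(report$delta_eff),
               n_total = report$n_total)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat("learning-curve report over", x$n_total, "samples\n")
  cat("empirical max accuracy:", round(x$empirical_max, 4), "\n")
  for (nm in names(x$efficiency)) {
    cat(sprintf("  Raghavan efficiency (%s): %.4f\n", nm, x$efficiency[[nm]]))
  }
  if (!is.null(x$mqe)) cat("  max query efficiency:", round(x$mqe, 4), "\n")
  if (!is.null(x$mig)) cat("  max information gain:", round(x$mig, 4), "\n")
  if (!is.null(x$delta_eff)) {
    cat(sprintf("  efficiency improvement: %+.2f%%\n", as.numeric(x$delta_eff)))
  }
  invisible(x)
}
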