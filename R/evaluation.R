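# Embedding evaluation measures: accuracy, Silhouette Index, score variance,
# empirical maximum, Raghavan efficiency, maximum query efficiency, maximum
# information gain, and the percentage efficiency improvement.

#' Confusion counts
#'
#' @param truth,pred vectors over \{+1, -1\}.
#' @return list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  list(TP = sum(truth == 1L & pred == 1L),
       TN = sum(truth == -1L & pred == -1L),
       FP = sum(truth == -1L & pred == 1L),
       FN = sum(truth == 1L & pred == -1L))
}

#' Classification accuracy
#'
#' phi_Acc = (TP + TN) / (TP + TN + FP + FN).
#'
#' @param TP,TN,FP,FN nonnegative confusion counts.
#' @return scalar in \[0, 1\].
#' @export
accuracy <- function(TP, TN, FP, FN) {
  total <- TP + TN + FP + FN
  if (total <= 0) stop("confusion counts sum to zero")
  (TP + TN) / total
}

#' Silhouette Index of a labelled embedding
#'
#' Binary-class silhouette: for each labelled sample, A_i is the mean
#' Euclidean distance (in the embedding) to the other samples of its own
#' class and B_i the mean distance to the other class; the index is the mean
#' over labelled samples of (B_i - A_i) / max(A_i, B_i), in \[-1, 1\].
#' Samples with max(A_i, B_i) = 0 (all coincident) contribute 0. Unlabelled
#' samples (label 0) are excluded from the score.
#'
#' @param Y embedding coordinates (or an `address_embedding`).
#' @param labels vector over \{+1, -1, 0\}.
#' @return scalar phi_SI in \[-1, 1\].
#' @export
silhouette_index <- function(Y, labels) {
  if (inherits(Y, "address_embedding")) Y <- Y$Y
  Y <- as.matrix(Y)
  labels <- check_labels(labels, nrow(Y))
  keep <- which(labels != 0L)
  y <- labels[keep]
  if (sum(y == 1L) < 2L || sum(y == -1L) < 2L) {
    stop("silhouette needs at least 2 labelled samples per class")
  }
  D <- as.matrix(stats::dist(Y[keep, , drop = FALSE]))
  same <- outer(y, y, "==")
  diag(same) <- NA  # exclude self from the own-class average
  A <- rowSums(D * (!is.na(same) & same), na.rm = TRUE) / (rowSums(same, na.rm = TRUE))
  B <- rowSums(D * outer(y, y, "!=")) / rowSums(outer(y, y, "!="))
  s <- ifelse(pmax(A, B) > 0, (B - A) / pmax(A, B), 0)
  mean(s)
}

#' Sample variance of repeated scores
#'
#' Variance across run repetitions of an accuracy or silhouette score,
#' sum((phi_i - mean)^2) / (n - 1); used for both rho_Acc and rho_SI.
#'
#' @param values numeric vector, length >= 2.
#' @return scalar variance.
#' @export
score_variance <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("score variance needs n >= 2 values")
  stats::var(values)
}

#' Empirical maximum accuracy
#'
#' The highest score observed over all runs and all label counts; the
#' performance ceiling used in the learning-rate measures.
#'
#' @param scores numeric vector or matrix (runs x label grid) of scores.
#' @return scalar maximum.
#' @export
empirical_max <- function(scores) {
  scores <- as.numeric(as.matrix(scores))
  if (length(scores) == 0L) stop("no scores supplied")
  max(scores)
}

#' Raghavan efficiency
#'
#' Area-ratio learning-rate measure comparing an active-learning accuracy
#' curve against a random-sampling curve on the same label-count grid:
#' phi_Eff = 1 - sum_t(ref - ac_t) / sum_t(ref - rd_t), where the reference
#' level `ref` is the random curve's final accuracy (`"final_random"`, the
#' default) or a supplied empirical-maximum ceiling (`"empirical_max"`).
#'
#' @param ac_curve mean active-learning accuracies per label count t.
#' @param rd_curve mean random-sampling accuracies on the same grid.
#' @param reference `"final_random"` or `"empirical_max"`.
#' @param empirical_max ceiling value, required for `"empirical_max"`.
#' @return scalar phi_Eff (1 = instant learning, 0 = no gain over random).
#' @export
raghavan_efficiency <- function(ac_curve, rd_curve,
                                reference = c("final_random", "empirical_max"),
                                empirical_max = NULL) {
  reference <- match.arg(reference)
  ac <- as.numeric(ac_curve)
  rd <- as.numeric(rd_curve)
  if (length(ac) != length(rd)) stop("curves must share the same t grid")
  ref <- if (reference == "final_random") {
    rd[length(rd)]
  } else {
    if (is.null(empirical_max)) stop("supply empirical_max for that reference")
    empirical_max
  }
  den <- sum(ref - rd)
  if (abs(den) < .Machine$double.eps * length(rd)) {
    stop("undefined efficiency: random-sampling curve already flat at the reference level")
  }
  1 - sum(ref - ac) / den
}

#' Maximum query efficiency
#'
#' Largest fraction of the total sample count saved in labels by active
#' learning: for each accuracy level reached by the active curve, the first
#' label counts at which each mean curve attains it (monotone step
#' interpolation on the running maximum, since raw curves need not be
#' monotone) are compared; phi_MQE = max over levels of (l_SS - l_Ad) / N.
#' Levels the random/SSAGE curve never reaches are excluded.
#'
#' @param ad_curve,ss_curve mean accuracies per label count for the active
#'   and random strategies, on the grid `n_labels`.
#' @param n_labels label counts of the grid (ascending).
#' @param n_total total number of samples N.
#' @return scalar phi_MQE.
#' @export
max_query_efficiency <- function(ad_curve, ss_curve, n_labels, n_total) {
  ad <- cummax(as.numeric(ad_curve))
  ss <- cummax(as.numeric(ss_curve))
  l <- as.numeric(n_labels)
  if (length(ad) != length(l) || length(ss) != length(l)) {
    stop("curves and n_labels must share a grid")
  }
  first_at <- function(curve, level) {
    hit <- which(curve >= level - 1e-12)
    if (length(hit) == 0L) NA_real_ else l[hit[1]]
  }
  levels <- unique(ad)
  gaps <- vapply(levels, function(a) {
    lad <- first_at(ad, a)
    lss <- first_at(ss, a)
    if (is.na(lss)) NA_real_ else (lss - lad) / n_total
  }, numeric(1))
  gaps <- gaps[!is.na(gaps)]
  if (length(gaps) == 0L) {
    stop("random-sampling curve never reaches any active-learning accuracy level")
  }
  max(gaps)
}

#' Maximum information gain
#'
#' Largest accuracy advantage of the active strategy at any label count:
#' phi_MIG = max_l (mean ad accuracy - mean ss accuracy).
#'
#' @param ad_curve,ss_curve mean accuracies on identical label grids.
#' @return scalar phi_MIG.
#' @export
max_information_gain <- function(ad_curve, ss_curve) {
  ad <- as.numeric(ad_curve)
  ss <- as.numeric(ss_curve)
  if (length(ad) != length(ss)) stop("curves must share the same label grid")
  max(ad - ss)
}

#' Percentage improvement in Raghavan efficiency
#'
#' Reported convention: (eff_ad / eff_ss - 1) x 100, positive when the
#' active learner is more efficient. The literal complementary form
#' (1 - eff_ad / eff_ss) x 100 is attached as attribute `"as_printed"`.
#'
#' @param eff_ad,eff_ss Raghavan efficiencies of the two strategies
#'   (eff_ss > 0).
#' @return percentage, with attribute `as_printed`.
#' @export
efficiency_improvement <- function(eff_ad, eff_ss) {
  if (eff_ss == 0) stop("baseline efficiency is zero; improvement undefined")
  ratio <- eff_ad / eff_ss
  structure((ratio - 1) * 100, as_printed = (1 - ratio) * 100)
}
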