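# Feature-selection consistency metrics across cross-validation folds:
# mean pairwise Jaccard, per-feature selection probability, the stable set
# at a selection-probability threshold, and the stability score (fraction of
# selected features that are stable).

#' Tolerance below which a coefficient counts as zero
#' @export
COEF_TOL <- 1e-10

#' Mean pairwise Jaccard index of fold feature sets
#'
#' (1 / C(N,2)) * sum over fold pairs of |Si intersect Sj| / |Si union Sj|.
#' A pair of empty sets is identical and contributes 1.
#'
#' @param sets list (length >= 2) of feature-identifier vectors.
#' @return mean pairwise Jaccard index in [0, 1].
#' @export
mean_pairwise_jaccard <- function(sets) {
  n <- length(sets)
  if (n < 2) stop("need at least 2 fold feature sets")
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      u <- length(union(sets[[i]], sets[[j]]))
      total <- total + if (u == 0) 1 else {
        length(intersect(sets[[i]], sets[[j]])) / u
      }
    }
  }
  total / choose(n, 2)
}

#' Per-feature selection probability across folds
#'
#' The proportion of folds in which a feature's coefficient is nonzero
#' (|beta| > [COEF_TOL]).
#'
#' @param fold_coefficients matrix with one column per fold and one row per
#'   feature (or a list of equal-length coefficient vectors).
#' @return named numeric vector of probabilities in [0, 1].
#' @export
selection_probability <- function(fold_coefficients) {
  if (is.list(fold_coefficients)) {
    lens <- lengths(fold_coefficients)
    if (length(unique(lens)) != 1) {
      stop("fold coefficient vectors must have equal length")
    }
    fold_coefficients <- do.call(cbind, fold_coefficients)
  }
  rowMeans(abs(fold_coefficients) > COEF_TOL)
}

#' Stable feature set at a selection-probability threshold
#'
#' @param pi_hat output of [selection_probability()].
#' @param pi_thr threshold in (0, 1]; a feature with probability exactly at
#'   the threshold is included.
#' @return indices (or names, if `pi_hat` is named) of stable features.
#' @export
stable_set <- function(pi_hat, pi_thr = 0.8) {
  if (pi_thr <= 0 || pi_thr > 1) stop("pi_thr must lie in (0, 1]")
  which(pi_hat >= pi_thr)
}

#' Stability score of a fit
#'
#' The fraction of selected features (union over folds) that belong to the
#' stable set; defined as 1 when no feature was ever selected.
#'
#' @param fold_sets list of per-fold selected feature index vectors.
#' @param stable stable feature indices from [stable_set()].
#' @return stability score in [0, 1].
#' @export
stability_score <- function(fold_sets, stable) {
  selected <- unique(unlist(fold_sets))
  if (length(selected) == 0) return(1)
  length(intersect(selected, stable)) / length(selected)
}

#' Full stability report for per-fold coefficients
#'
#' @inheritParams selection_probability
#' @param pi_thr selection-probability threshold.
#' @return list with `jaccard`, `pi_hat`, `stable_set`, `stability`,
#'   `fold_sets`.
#' @export
stability_report <- function(fold_coefficients, pi_thr = 0.8) {
  if (is.list(fold_coefficients)) {
    fold_coefficients <- do.call(cbind, fold_coefficients)
  }
  fold_sets <- apply(abs(fold_coefficients) > COEF_TOL, 2, which,
                     simplify = FALSE)
  pi_hat <- selection_probability(fold_coefficients)
  st <- stable_set(pi_hat, pi_thr)
  list(jaccard = mean_pairwise_jaccard(fold_sets),
       pi_hat = pi_hat,
       stable_set = st,
       stability = stability_score(fold_sets, st),
       fold_sets = fold_sets)
}
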