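# Baseline bladder-volume estimators: elastic-net regression on the 90
# measurement-frame features, either patient-specific (leave-one-measurement-
# out within each virtual patient) or generalized (leave-one-patient-out,
# with waist and fat appended as features). Hyperparameters are grid-searched
# on the cross-validated scoring metric pooled over all folds, yielding a
# single optimum per model.

#' Default elastic-net hyperparameter grid
#'
#' Penalty weights log-spaced over 1e-7..1e-1 (25 points) and L1 ratios
#' 0.1..1.0 in steps of 0.1.
#'
#' @param n_lambda number of penalty weights.
#' @return list with `lambda` and `l1_ratio` vectors.
#' @export
default_hyper_grid <- function(n_lambda = 25) {
  list(lambda = 10^seq(-7, -1, length.out = n_lambda),
       l1_ratio = seq(0.1, 1, by = 0.1))
}

# Single elastic-net fit along a lambda path at fixed l1 ratio.
# Returns predict(newx, lambda), predict_grid(newx) over the whole grid
# (columns in the order of `lambdas` sorted decreasing), and coef(lambda).
enet_path <- function(x, y, l1_ratio, lambdas) {
  lambdas <- sort(lambdas, decreasing = TRUE)
  if (stats::sd(y) == 0) {
    # degenerate: intercept-only model at every penalty
    mu <- y[1]
    return(list(predict = function(newx, lambda) rep(mu, nrow(newx)),
                predict_grid = function(newx) {
                  matrix(mu, nrow(newx), length(lambdas))
                },
                coef = function(lambda) numeric(ncol(x))))
  }
  pad <- ncol(x) == 1  # glmnet needs >= 2 columns
  if (pad) x <- cbind(x, 0)
  # warm-start ramp: coordinate descent needs a path starting near the
  # data-driven lambda_max; grid values are typically far below it
  n <- nrow(x)
  sdv <- apply(x, 2, function(c) sqrt(sum((c - mean(c))^2) / n))
  xs <- sweep(x, 2, colMeans(x))
  xs <- sweep(xs, 2, ifelse(sdv > 0, sdv, 1), "/")
  lam_max <- max(abs(crossprod(xs, y - mean(y)))) / n / max(l1_ratio, 1e-3)
  ramp <- numeric(0)
  if (lam_max > max(lambdas)) {
    ramp <- exp(seq(log(lam_max * 1.05), log(max(lambdas)),
                    length.out = 12))[-12]
  }
  # extreme grid penalties on saturated problems routinely hit the
  # iteration cap; those grid points simply score poorly in the search,
  # so the per-lambda convergence warnings are noise here
  fit <- suppressWarnings(
    glmnet::glmnet(x, y, family = "gaussian", alpha = l1_ratio,
                   lambda = c(ramp, lambdas), standardize = TRUE,
                   maxit = 1e5, thresh = 1e-10))
  list(predict = function(newx, lambda) {
    if (pad) newx <- cbind(newx, 0)
    as.numeric(glmnet::predict.glmnet(fit, newx, s = lambda, exact = FALSE))
  },
  predict_grid = function(newx) {
    if (pad) newx <- cbind(newx, 0)
    unname(as.matrix(glmnet::predict.glmnet(fit, newx, s = lambdas,
                                            exact = FALSE)))
  },
  coef = function(lambda) {
    b <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))[-1]
    if (pad) b <- b[1]
    b
  })
}

score_errors <- function(pred, truth, scoring) {
  switch(scoring,
         mae = mean(abs(pred - truth)),
         mape = mean(abs(pred - truth) / truth) * 100,
         stop("unknown scoring metric"))
}

# Cross-validated grid search over (lambda, l1_ratio). `folds` is a list of
# list(train, test, group) row-index sets. The chosen point minimizes the
# scoring metric pooled over all held-out predictions; ties break to the
# smallest lambda, then the smallest l1 ratio.
enet_cv <- function(x, y, folds, grid, scoring) {
  n_lam <- length(grid$lambda)
  n_alp <- length(grid$l1_ratio)
  lam_sorted <- sort(grid$lambda)
  test_idx <- unlist(lapply(folds, `[[`, "test"))
  preds <- array(NA_real_, c(length(test_idx), n_lam, n_alp))

  for (ai in seq_len(n_alp)) {
    row0 <- 0
    for (f in folds) {
      path <- enet_path(x[f$train, , drop = FALSE], y[f$train],
                        grid$l1_ratio[ai], lam_sorted)
      pg <- path$predict_grid(x[f$test, , drop = FALSE])
      # predict_grid columns follow decreasing lambda; map onto lam_sorted
      preds[row0 + seq_along(f$test), , ai] <- pg[, n_lam:1, drop = FALSE]
      row0 <- row0 + length(f$test)
    }
  }
  truth <- y[test_idx]
  scores <- apply(preds, c(2, 3), score_errors, truth = truth,
                  scoring = scoring)
  best <- which(scores == min(scores), arr.ind = TRUE)
  # ties: smallest penalty first, then smallest l1 ratio
  best <- best[order(lam_sorted[best[, 1]], grid$l1_ratio[best[, 2]]), ,
               drop = FALSE][1, ]
  lambda <- lam_sorted[best[1]]
  l1_ratio <- grid$l1_ratio[best[2]]

  # refit each fold at the chosen hyperparameters for coefficients
  coefs <- matrix(NA_real_, ncol(x), length(folds))
  rownames(coefs) <- colnames(x)
  fold_rows <- list()
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    path <- enet_path(x[f$train, , drop = FALSE], y[f$train],
                      l1_ratio, lam_sorted)
    coefs[, fi] <- path$coef(lambda)
    fold_rows[[fi]] <- data.frame(
      group = f$group, fold = fi, row = f$test, truth = y[f$test],
      pred = path$predict(x[f$test, , drop = FALSE], lambda))
  }
  surface <- data.frame(lambda = rep(lam_sorted, n_alp),
                        l1_ratio = rep(grid$l1_ratio, each = n_lam),
                        score = as.vector(scores))
  list(lambda = lambda, l1_ratio = l1_ratio, scoring = scoring,
       cv_surface = surface, folds = do.call(rbind, fold_rows),
       coefs = coefs)
}

select_slice <- function(signal_table, frequency_hz) {
  if (!is.null(frequency_hz)) {
    sel <- abs(signal_table$frequency_hz - frequency_hz) < 1e-9
    if (!any(sel)) stop("no rows at the requested frequency")
    signal_table <- signal_table[sel, , drop = FALSE]
  }
  signal_table
}

#' Fit patient-specific volume estimators
#'
#' One elastic-net model per virtual patient, evaluated by leave-one-out
#' cross-validation over that patient's measurements (5 non-baseline
#' volumes: train on 4, predict 1). A single hyperparameter pair is chosen
#' by minimizing the scoring metric pooled over all patients' held-out
#' predictions.
#'
#' @param signal_table a `dv` or `vcr` table from [build_voltage_table()]
#'   (or [synthetic_voltage_table()] after baseline differencing).
#' @param scoring `"mae"` (mL) or `"mape"` (percent).
#' @param grid hyperparameter grid, see [default_hyper_grid()].
#' @param frequency_hz frequency slice to train on (default 50 kHz);
#'   `NULL` pools all frequencies.
#' @return a `bs_fit` object; see [model_report()].
#' @export
fit_patient_specific <- function(signal_table, scoring = c("mae", "mape"),
                                 grid = default_hyper_grid(),
                                 frequency_hz = 50e3) {
  scoring <- match.arg(scoring)
  tab <- select_slice(signal_table, frequency_hz)
  fcols <- frame_columns(tab)
  x <- as.matrix(tab[, fcols])
  y <- tab$volume_ml

  folds <- list()
  for (pid in unique(tab$patient_id)) {
    rows <- which(tab$patient_id == pid)
    if (length(rows) < 2) stop(sprintf("patient %s has < 2 rows", pid))
    for (r in rows) {
      folds[[length(folds) + 1]] <-
        list(train = setdiff(rows, r), test = r, group = pid)
    }
  }
  fit <- enet_cv(x, y, folds, grid, scoring)
  fit$model <- "patient_specific"
  fit$n_features <- length(fcols)
  fit$frame_features <- fcols
  class(fit) <- "bs_fit"
  fit
}

#' Fit the generalized volume estimator
#'
#' One elastic net over all virtual patients with waist circumference and
#' fat thickness appended as features (92 features for the 6-electrode
#' belt), evaluated by leave-one-patient-out cross-validation (15 folds for
#' the default grid).
#'
#' @inheritParams fit_patient_specific
#' @return a `bs_fit` object.
#' @export
fit_generalized <- function(signal_table, scoring = c("mae", "mape"),
                            grid = default_hyper_grid(),
                            frequency_hz = 50e3) {
  scoring <- match.arg(scoring)
  tab <- select_slice(signal_table, frequency_hz)
  if (length(unique(tab$patient_id)) < 2) stop("need at least 2 patients")
  if (!all(c("waist_m", "fat_m") %in% names(tab))) {
    stop("missing patient metadata (waist_m, fat_m)")
  }
  fcols <- frame_columns(tab)
  x <- cbind(as.matrix(tab[, fcols]),
             waist_m = tab$waist_m, fat_m = tab$fat_m)
  y <- tab$volume_ml

  folds <- lapply(unique(tab$patient_id), function(pid) {
    rows <- which(tab$patient_id == pid)
    list(train = which(tab$patient_id != pid), test = rows, group = pid)
  })
  fit <- enet_cv(x, y, folds, grid, scoring)
  fit$model <- "generalized"
  fit$n_features <- ncol(x)
  fit$frame_features <- fcols
  class(fit) <- "bs_fit"
  fit
}

#' @export
print.bs_fit <- function(x, ...) {
  cat(sprintf("<bs_fit: %s, scoring = %s, lambda = %.3g, l1 = %.2f>\n",
              x$model, x$scoring, x$lambda, x$l1_ratio))
  invisible(x)
}

#' Cross-validation report for a fitted model
#'
#' Aggregates held-out errors, selected-feature counts, neighbor-set usage
#' and feature-selection stability into one row of summary statistics per
#' fitted model. Errors are summarized per patient for
#' patient-specific fits and per fold for generalized fits (mean and sample
#' standard deviation across those groups).
#'
#' @param fit a `bs_fit`.
#' @param frames frame metadata from [enumerate_frames()]; used for the
#'   neighbor-set fraction F_N = |selected frames in N| / |N|.
#' @param pi_thr stable-set selection-probability threshold.
#' @return a `model_report` list.
#' @export
model_report <- function(fit, frames = enumerate_frames(6), pi_thr = 0.8) {
  stopifnot(inherits(fit, "bs_fit"))
  f <- fit$folds
  per_group <- function(metric) {
    v <- vapply(split(f, f$group), function(d) {
      score_errors(d$pred, d$truth, metric)
    }, numeric(1))
    c(mean = mean(v), sd = stats::sd(v))
  }
  mae <- per_group("mae")
  mape <- per_group("mape")

  sel <- abs(fit$coefs) > COEF_TOL
  n_sel <- colSums(sel)
  n_set <- frames$frame[frames$in_neighbor_set]
  frame_rows <- match(fit$frame_features, rownames(fit$coefs))
  fn_per_fold <- vapply(seq_len(ncol(sel)), function(fi) {
    chosen <- rownames(fit$coefs)[frame_rows][sel[frame_rows, fi]]
    length(intersect(chosen, n_set)) / length(n_set)
  }, numeric(1))

  st <- stability_report(fit$coefs, pi_thr)
  structure(list(
    model = fit$model, scoring = fit$scoring,
    lambda = fit$lambda, l1_ratio = fit$l1_ratio,
    mae_mean = mae["mean"], mae_sd = mae["sd"],
    mape_mean = mape["mean"], mape_sd = mape["sd"],
    n_features_mean = mean(n_sel), n_features_sd = stats::sd(n_sel),
    f_n = mean(fn_per_fold),
    jaccard = st$jaccard, stability = st$stability,
    stable_set = st$stable_set
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report: %s (%s-optimized)>\n", x$model, x$scoring))
  cat(sprintf("  MAE  %6.2f +/- %5.2f mL   MAPE %6.2f +/- %5.2f %%\n",
              x$mae_mean, x$mae_sd, x$mape_mean, x$mape_sd))
  cat(sprintf("  features %5.2f +/- %4.2f   F_N %.2f   J %.2f   S %.2f\n",
              x$n_features_mean, x$n_features_sd, x$f_n, x$jaccard,
              x$stability))
  invisible(x)
}
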