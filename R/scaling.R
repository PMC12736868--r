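# Anatomical frame scaling: one multiplicative normalization factor per
# measurement row, a function of waist circumference w and fat thickness f
# only, applied uniformly to all frame features. Two laws:
#   linear:       Vs = V / (alpha_lin * w * beta_lin * f)
#   exponential:  Vs = V * (eta * exp(-delta1 * w - delta2 * f) + alpha_off)
# Parameters are fitted on training patients by collapsing every anatomy
# onto a common reference curve: the training-pool mean signal per volume on
# the elastic-net-selected features.

#' Construct scaling parameters
#'
#' @param method `"linear"` or `"exponential"`.
#' @param alpha_lin,beta_lin linear coefficients (only their product is
#'   identifiable; the fit keeps `beta_lin = 1`).
#' @param eta,delta1,delta2,alpha_off exponential gain, waist and fat decay
#'   rates (1/m) and offset.
#' @param features feature names the parameters were fitted on.
#' @return a `scaling_params` object.
#' @export
scaling_params <- function(method = c("linear", "exponential"),
                           alpha_lin = 1, beta_lin = 1,
                           eta = 1, delta1 = 0, delta2 = 0, alpha_off = 0,
                           features = NULL) {
  method <- match.arg(method)
  structure(list(method = method, alpha_lin = alpha_lin,
                 beta_lin = beta_lin, eta = eta, delta1 = delta1,
                 delta2 = delta2, alpha_off = alpha_off,
                 features = features),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  if (x$method == "linear") {
    cat(sprintf("<scaling_params: linear, alpha*beta = %.4g>\n",
                x$alpha_lin * x$beta_lin))
  } else {
    cat(sprintf(
      "<scaling_params: exponential, eta = %.4g, delta = (%.3g, %.3g), offset = %.4g>\n",
      x$eta, x$delta1, x$delta2, x$alpha_off))
  }
  invisible(x)
}

#' Row multiplier of a scaling law
#'
#' @param p a `scaling_params`.
#' @param w waist circumference (m), vectorized.
#' @param f fat thickness (m), vectorized.
#' @return the factor each frame voltage of the row is multiplied by.
#' @export
scaling_multiplier <- function(p, w, f) {
  stopifnot(inherits(p, "scaling_params"))
  if (p$method == "linear") {
    den <- p$alpha_lin * w * p$beta_lin * f
    if (any(den <= 0)) stop("non-positive linear scaling denominator")
    1 / den
  } else {
    m <- p$eta * exp(-p$delta1 * w - p$delta2 * f) + p$alpha_off
    if (any(m <= 0)) stop("non-positive exponential scaling multiplier")
    m
  }
}

#' Linear frame scaling (one factor per row)
#'
#' @param v numeric vector or matrix of frame voltages (rows = measurements).
#' @param w,f anatomy of each row (scalars or per-row vectors).
#' @param p `scaling_params` with method `"linear"`.
#' @return scaled signal of the same shape.
#' @export
linear_scale <- function(v, w, f, p) {
  stopifnot(p$method == "linear")
  apply_multiplier(v, scaling_multiplier(p, w, f))
}

#' Exponential frame scaling (one factor per row)
#'
#' @inheritParams linear_scale
#' @param p `scaling_params` with method `"exponential"`.
#' @return scaled signal of the same shape.
#' @export
exp_scale <- function(v, w, f, p) {
  stopifnot(p$method == "exponential")
  apply_multiplier(v, scaling_multiplier(p, w, f))
}

apply_multiplier <- function(v, m) {
  if (is.matrix(v)) {
    stopifnot(length(m) == 1 || length(m) == nrow(v))
    v * m
  } else {
    v * m
  }
}

#' Fit scaling parameters on training rows
#'
#' Minimizes, over the training rows only, the squared distance between the
#' scaled signal and the training-pool mean signal per volume (the common
#' reference curve), restricted to the elastic-net-selected features. The
#' linear law reduces to a closed-form one-dimensional least squares (only
#' the product alpha*beta is identifiable; beta is fixed at 1). The
#' exponential law is fitted by Levenberg-Marquardt, initialized from a
#' log-linear regression of the per-row mean-signal ratio on (w, f).
#'
#' @param train a signal table subset (training patients only).
#' @param method `"linear"` or `"exponential"`.
#' @param features frame columns to fit on (default: all frames).
#' @return fitted `scaling_params`.
#' @export
fit_scaling <- function(train, method = c("linear", "exponential"),
                        features = NULL) {
  method <- match.arg(method)
  if (is.null(features)) features <- frame_columns(train)
  if (length(features) == 0) stop("empty feature set")
  if (nrow(unique(train[, c("waist_m", "fat_m")])) < 2) {
    stop("need >= 2 distinct (waist, fat) anatomies to fit scaling")
  }
  v <- as.matrix(train[, features, drop = FALSE])
  w <- train$waist_m
  f <- train$fat_m
  vols <- train$volume_ml
  vref <- ref_curve(v, vols)
  target <- vref[match(vols, as.numeric(rownames(vref))), , drop = FALSE]

  if (method == "linear") {
    vw <- v / (w * f)
    u <- sum(vw * target) / sum(vw * vw)   # Vs = u * V/(w f)
    p <- scaling_params("linear", alpha_lin = 1 / u, beta_lin = 1,
                        features = features)
    scaling_multiplier(p, w, f)  # validates positivity on the training range
    return(p)
  }

  ratio <- rowMeans(target) / rowMeans(v)
  init_fit <- stats::lm(log(ratio) ~ w + f)
  start <- c(eta = exp(unname(stats::coef(init_fit)[1])),
             delta1 = -unname(stats::coef(init_fit)[2]),
             delta2 = -unname(stats::coef(init_fit)[3]),
             alpha_off = 0)
  resid_fn <- function(par) {
    m <- par[1] * exp(-par[2] * w - par[3] * f) + par[4]
    as.vector(v * m - target)
  }
  nls <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (nls$info == 0 || nls$info == 9) {
    stop(sprintf("scaling fit did not converge (residual %.4g)",
                 sqrt(sum(nls$fvec^2))))
  }
  par <- unname(nls$par)
  p <- scaling_params("exponential", eta = par[1], delta1 = par[2],
                      delta2 = par[3], alpha_off = par[4],
                      features = features)
  scaling_multiplier(p, w, f)
  p
}

ref_curve <- function(v, vols) {
  uv <- sort(unique(vols))
  out <- t(vapply(uv, function(x) colMeans(v[vols == x, , drop = FALSE]),
                  numeric(ncol(v))))
  rownames(out) <- uv
  out
}

scale_table <- function(table, p) {
  fcols <- frame_columns(table)
  m <- scaling_multiplier(p, table$waist_m, table$fat_m)
  table[, fcols] <- as.matrix(table[, fcols]) * m
  table
}

#' Evaluate the generalized estimator on scaled inputs
#'
#' Fully nested leave-one-patient-out evaluation: within each outer fold the
#' scaling parameters are fitted on the training patients only, both
#' partitions are scaled, the generalized elastic net is grid-searched by
#' patient-level cross-validation inside the training partition, refitted on
#' all scaled training rows, and the held-out patient is predicted. No
#' information from the held-out patient enters scaling or model selection.
#'
#' @param signal_table a `dv` or `vcr` table.
#' @param method `"linear"`, `"exponential"`, or `"none"` (no scaling).
#' @param feature_set frame columns used to fit the scaling (e.g. the stable
#'   set of an unscaled fit); default all frames.
#' @param scoring inner model-selection metric, `"mae"` or `"mape"`.
#' @param grid hyperparameter grid for the inner search.
#' @param frequency_hz frequency slice (default 50 kHz).
#' @param params optional fixed `scaling_params` applied in every fold
#'   instead of fitting (e.g. identity parameters).
#' @param inner_k number of patient-level groups for the inner
#'   model-selection cross-validation (training patients are assigned
#'   round-robin in their table order).
#' @return a `scaled_report` with per-fold errors and fitted scaling
#'   parameters.
#' @export
evaluate_scaled <- function(signal_table,
                            method = c("linear", "exponential", "none"),
                            feature_set = NULL,
                            scoring = c("mae", "mape"),
                            grid = default_hyper_grid(),
                            frequency_hz = 50e3,
                            params = NULL,
                            inner_k = 5) {
  method <- match.arg(method)
  scoring <- match.arg(scoring)
  tab <- select_slice(signal_table, frequency_hz)
  pids <- unique(tab$patient_id)
  if (length(pids) < 2) stop("need at least 2 patients")
  fcols <- frame_columns(tab)
  if (is.null(feature_set)) feature_set <- fcols

  fold_rows <- list()
  fold_params <- list()
  for (pid in pids) {
    train <- tab[tab$patient_id != pid, , drop = FALSE]
    test <- tab[tab$patient_id == pid, , drop = FALSE]
    p <- NULL
    if (method != "none") {
      p <- if (!is.null(params)) params else {
        fit_scaling(train, method, feature_set)
      }
      train <- scale_table(train, p)
      test <- scale_table(test, p)
    }
    x_tr <- cbind(as.matrix(train[, fcols]),
                  waist_m = train$waist_m, fat_m = train$fat_m)
    x_te <- cbind(as.matrix(test[, fcols]),
                  waist_m = test$waist_m, fat_m = test$fat_m)
    y_tr <- train$volume_ml

    tr_pids <- unique(train$patient_id)
    grp <- rep_len(seq_len(min(inner_k, length(tr_pids))), length(tr_pids))
    inner <- lapply(unique(grp), function(gi) {
      held <- tr_pids[grp == gi]
      list(train = which(!train$patient_id %in% held),
           test = which(train$patient_id %in% held),
           group = paste0("G", gi))
    })
    cv <- enet_cv(x_tr, y_tr, inner, grid, scoring)
    final <- enet_path(x_tr, y_tr, cv$l1_ratio,
                       sort(grid$lambda, decreasing = TRUE))
    pred <- final$predict(x_te, cv$lambda)
    fold_rows[[pid]] <- data.frame(group = pid, truth = test$volume_ml,
                                   pred = pred)
    fold_params[[pid]] <- p
  }
  f <- do.call(rbind, fold_rows)
  per_fold <- function(metric) {
    v <- vapply(split(f, f$group), function(d) {
      score_errors(d$pred, d$truth, metric)
    }, numeric(1))
    c(mean = mean(v), sd = stats::sd(v))
  }
  mae <- per_fold("mae")
  mape <- per_fold("mape")
  structure(list(method = method, scoring = scoring,
                 feature_set = feature_set,
                 mae_mean = mae["mean"], mae_sd = mae["sd"],
                 mape_mean = mape["mean"], mape_sd = mape["sd"],
                 folds = f, fold_params = fold_params),
            class = "scaled_report")
}

#' @export
print.scaled_report <- function(x, ...) {
  cat(sprintf(
    "<scaled_report: %s scaling (%s-selected), MAE %.2f +/- %.2f mL, MAPE %.2f +/- %.2f %%>\n",
    x$method, x$scoring, x$mae_mean, x$mae_sd, x$mape_mean, x$mape_sd))
  invisible(x)
}
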