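test_that("vanishing penalty reproduces the least-squares oracle", {
  set.seed(11)
  x <- matrix(rnorm(60), 20, 3)
  y <- as.numeric(x %*% c(1.5, -2, 3)) + rnorm(20, 0, 0.05)
  path <- bladdersim:::enet_path(x, y, l1_ratio = 0.5,
                                 lambdas = c(1e-1, 1e-4, 1e-9))
  ols <- unname(coef(lm(y ~ x)))[-1]
  expect_lt(max(abs(path$coef(1e-9) - ols)), 1e-6)
  expect_lt(max(abs(path$predict(x, 1e-9) - unname(fitted(lm(y ~ x))))),
            1e-5)
})

test_that("noiseless within-patient linear data is recovered exactly", {
  fp <- fit_patient_specific(syn_tabs_clean$dv, "mae", small_grid)
  r <- model_report(fp)
  expect_lt(r$mae_mean, 0.5)
  expect_lt(r$mape_mean, 0.5)
})

test_that("constant target volumes give an intercept-only model", {
  raw <- syn_raw_clean[syn_raw_clean$patient_id %in% c("P01", "P02"), ]
  raw$volume_ml[raw$volume_ml != 10] <- 99   # collapse to one level
  raw <- raw[!duplicated(paste(raw$patient_id, raw$volume_ml)) |
               raw$volume_ml == 99, ]
  tabs <- build_voltage_table(raw)
  fp <- fit_patient_specific(tabs$dv, "mae", small_grid)
  r <- model_report(fp)
  expect_equal(r$mae_mean, 0, ignore_attr = TRUE)
  expect_equal(r$n_features_mean, 0)
})

test_that("the generalized design has 92 features and patient-level folds", {
  fg <- fit_generalized(syn_tabs_clean$dv, "mae", small_grid)
  expect_equal(nrow(fg$coefs), 92)
  expect_equal(ncol(fg$coefs), 15)
  expect_true(all(c("waist_m", "fat_m") %in% rownames(fg$coefs)))
  # patient-shifted data: held-out error is much worse than within-patient
  rp <- model_report(fit_patient_specific(syn_tabs_clean$dv, "mae",
                                          small_grid))
  rg <- model_report(fg)
  expect_gt(rg$mae_mean, rp$mae_mean)
})

test_that("shared-structure data lets the generalized model interpolate", {
  pat <- enumerate_sweep(sweep_grid())$patients
  raw <- synthetic_voltage_table(pat, delta_sens = c(0, 0),
                                 delta_base = c(0, 0), noise_cv = 0,
                                 seed = 8)
  tabs <- build_voltage_table(raw)
  rg <- model_report(fit_generalized(tabs$dv, "mae", small_grid))
  expect_lt(rg$mae_mean, 0.5)
})

test_that("grid search tie-breaks to the smallest penalty then l1 ratio", {
  one <- list(lambda = 1e-3, l1_ratio = 0.7)
  fp <- fit_patient_specific(syn_tabs_clean$dv, "mae", one)
  expect_equal(fp$lambda, 1e-3)
  expect_equal(fp$l1_ratio, 0.7)
  expect_equal(nrow(fp$cv_surface), 1)
  # a duplicated-score grid (same lambda twice via l1 with zero features)
  raw <- syn_raw_clean[syn_raw_clean$patient_id %in% c("P01", "P02"), ]
  raw$volume_ml[raw$volume_ml != 10] <- 99
  tabs <- build_voltage_table(raw)
  tie <- list(lambda = c(1e-3, 1e-2), l1_ratio = c(0.5, 1))
  ft <- fit_patient_specific(tabs$dv, "mae", tie)
  expect_equal(ft$lambda, 1e-3)   # all scores equal -> smallest penalty
  expect_equal(ft$l1_ratio, 0.5)
})

test_that("report arithmetic matches hand computation on a toy fit", {
  frames <- enumerate_frames(6)
  coefs <- matrix(0, 92, 2)
  rownames(coefs) <- c(frames$frame, "waist_m", "fat_m")
  coefs["cc12_pu34", 1] <- 1     # a neighbor-set frame
  coefs["cc12_pu34", 2] <- 1
  coefs["cc14_pu25", 2] <- -2    # not in the neighbor set
  fit <- structure(list(
    model = "generalized", scoring = "mae", lambda = 1, l1_ratio = 1,
    folds = data.frame(group = c("A", "A", "B", "B"),
                       truth = c(100, 200, 100, 200),
                       pred = c(110, 190, 120, 230)),
    coefs = coefs, n_features = 92, frame_features = frames$frame
  ), class = "bs_fit")
  r <- model_report(fit)
  # per-group MAE: A = 10, B = 25
  expect_equal(unname(r$mae_mean), 17.5)
  expect_equal(unname(r$mae_sd), sd(c(10, 25)))
  # per-group MAPE: A = (10 + 5) / 2 = 7.5%, B = (20 + 15) / 2 = 17.5%
  expect_equal(unname(r$mape_mean), 12.5)
  expect_equal(r$n_features_mean, 1.5)
  # fold 1 uses 1 of 12 neighbor frames, fold 2 also 1 of 12
  expect_equal(r$f_n, 1 / 12)
  # all-zero coefficients: no features, F_N = 0, stability defined as 1
  fit0 <- fit
  fit0$coefs <- matrix(0, 92, 2, dimnames = dimnames(coefs))
  r0 <- model_report(fit0)
  expect_equal(r0$n_features_mean, 0)
  expect_equal(r0$f_n, 0)
  expect_equal(r0$stability, 1)
  # every frame selected in every fold: F_N = 1
  fit1 <- fit
  fit1$coefs <- matrix(1, 92, 2, dimnames = dimnames(coefs))
  expect_equal(model_report(fit1)$f_n, 1)
})

test_that("a planted 5-frame support lands in the stable set", {
  frames <- enumerate_frames(6)$frame
  support <- frames[c(3, 17, 41, 60, 88)]
  hits <- 0
  n_rep <- 5
  for (s in 1:n_rep) {
    set.seed(100 + s)
    # frames vary independently; volume is a positive combination of the
    # support frames plus small noise, identical law for every patient
    n_pat <- 6
    rows <- list()
    for (p in 1:n_pat) {
      for (rep in 1:5) {
        row <- data.frame(patient_id = sprintf("S%02d", p),
                          waist_m = 0.9, fat_m = 0.04,
                          volume_ml = NA_real_, frequency_hz = 5e4)
        vals <- runif(90, 0.5, 2)
        row[frames] <- as.list(vals)
        rows[[length(rows) + 1]] <- row
      }
    }
    tab <- do.call(rbind, rows)
    x <- as.matrix(tab[, frames])
    tab$volume_ml <- as.numeric(x[, support] %*% c(40, 60, 80, 100, 120)) +
      rnorm(nrow(tab), 0, 0.5)
    fit <- fit_generalized(tab, "mae",
                           list(lambda = 10^seq(-3, -1, length.out = 5),
                                l1_ratio = 1))
    st <- stability_report(fit$coefs[frames, ])
    stable_frames <- frames[st$stable_set]
    if (all(support %in% stable_frames)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
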