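test_that("linear scaling follows its closed form and preserves ratios", {
  p <- scaling_params("linear", alpha_lin = 1, beta_lin = 1)
  expect_equal(linear_scale(3.3, w = 1, f = 1, p), 3.3)
  p2 <- scaling_params("linear", alpha_lin = 2, beta_lin = 4)
  expect_equal(linear_scale(2, w = 0.5, f = 0.25, p2), 2)  # unit denominator
  # one factor per row: within-row frame ratios are preserved exactly
  v <- matrix(c(1, 2, 4, 3, 6, 12), 2, 3, byrow = TRUE)
  sv <- linear_scale(v, w = c(0.8, 1.2), f = c(0.02, 0.06), p)
  expect_equal(sv[1, 2] / sv[1, 1], v[1, 2] / v[1, 1])
  expect_equal(sv[2, 3] / sv[2, 1], v[2, 3] / v[2, 1])
  expect_error(scaling_multiplier(p, w = -1, f = 0.05), "denominator")
})

test_that("exponential scaling follows its closed form", {
  id <- scaling_params("exponential", eta = 1, delta1 = 0, delta2 = 0,
                       alpha_off = 0)
  expect_equal(exp_scale(7.7, w = 1.1, f = 0.04, id), 7.7)
  gain <- scaling_params("exponential", eta = 0, alpha_off = 2.5)
  expect_equal(exp_scale(3, w = 1, f = 0.02, gain), 7.5)
  # positive waist decay means a strictly decreasing multiplier in waist
  p <- scaling_params("exponential", eta = 1, delta1 = 2, delta2 = 0,
                      alpha_off = 0)
  m <- scaling_multiplier(p, w = c(0.8, 1.0, 1.2), f = 0.02)
  expect_true(all(diff(m) < 0))
  bad <- scaling_params("exponential", eta = -1, alpha_off = 0)
  expect_error(scaling_multiplier(bad, 1, 0.02), "multiplier")
})

test_that("fitting requires anatomical contrast and a feature set", {
  one <- syn_raw_clean[syn_raw_clean$patient_id == "P01", ]
  expect_error(fit_scaling(one, "exponential"), "distinct")
  expect_error(fit_scaling(syn_raw_clean, "linear", character(0)), "empty")
})

test_that("planted exponential law is recovered (noiseless within 1%)", {
  true_p <- scaling_params("exponential", eta = 0.8, delta1 = -2.5,
                           delta2 = -12, alpha_off = 0.15)
  raw <- plant_exp_law(true_p, noise_cv = 0, seed = 5)
  fit <- fit_scaling(raw, "exponential")
  # the reference-collapse objective determines the multiplier up to the
  # pooled-mean normalization c = mean over patients of 1 / m*(w, f)
  pats <- unique(raw[, c("waist_m", "fat_m")])
  cc <- mean(1 / scaling_multiplier(true_p, pats$waist_m, pats$fat_m))
  expect_equal(fit$delta1, true_p$delta1, tolerance = 0.01)
  expect_equal(fit$delta2, true_p$delta2, tolerance = 0.01)
  expect_equal(fit$eta / cc, true_p$eta, tolerance = 0.01)
  expect_equal(fit$alpha_off / cc, true_p$alpha_off, tolerance = 0.01)
})

test_that("planted law survives 1% multiplicative noise (within 10%)", {
  true_p <- scaling_params("exponential", eta = 0.8, delta1 = -2.5,
                           delta2 = -12, alpha_off = 0.15)
  for (seed in c(21, 22)) {
    raw <- plant_exp_law(true_p, noise_cv = 0.01, seed = seed)
    fit <- fit_scaling(raw, "exponential")
    pats <- unique(raw[, c("waist_m", "fat_m")])
    cc <- mean(1 / scaling_multiplier(true_p, pats$waist_m, pats$fat_m))
    expect_equal(fit$delta1, true_p$delta1, tolerance = 0.1)
    expect_equal(fit$delta2, true_p$delta2, tolerance = 0.1)
    expect_equal(fit$eta / cc, true_p$eta, tolerance = 0.1)
  }
})

test_that("linear fit collapses a pure product law", {
  # data generated as V = V_ref * (3 w f): dividing by a fitted product law
  # collapses every anatomy onto a common per-volume curve
  pat <- enumerate_sweep(sweep_grid())$patients
  raw <- synthetic_voltage_table(pat, delta_sens = c(0, 0),
                                 delta_base = c(0, 0), seed = 6)
  fcols <- frame_columns(raw)
  raw[, fcols] <- as.matrix(raw[, fcols]) * (3 * raw$waist_m * raw$fat_m)
  fit <- fit_scaling(raw, "linear")
  m <- scaling_multiplier(fit, raw$waist_m, raw$fat_m)
  scaled <- as.matrix(raw[, fcols]) * m
  # all patients collapse onto a common per-volume curve
  for (v in unique(raw$volume_ml)) {
    block <- scaled[raw$volume_ml == v, ]
    expect_lt(max(apply(block, 2, sd) / colMeans(block)), 1e-8)
  }
})

test_that("a mean-one multiplier leaves a constant table's pooled mean intact", {
  pat <- enumerate_sweep(sweep_grid())$patients
  raw <- synthetic_voltage_table(pat, delta_sens = c(0, 0),
                                 delta_base = c(0, 0), sens_range = c(0, 0),
                                 seed = 9)
  fcols <- frame_columns(raw)
  wf <- raw$waist_m * raw$fat_m
  p <- scaling_params("linear", alpha_lin = mean(1 / wf), beta_lin = 1)
  m <- scaling_multiplier(p, raw$waist_m, raw$fat_m)
  scaled <- as.matrix(raw[, fcols]) * m
  expect_equal(mean(m), 1, tolerance = 1e-12)
  expect_equal(mean(scaled), mean(as.matrix(raw[, fcols])),
               tolerance = 1e-10)
})

test_that("identity scaling reproduces the unscaled generalized evaluation", {
  g <- list(lambda = 10^seq(-6, -2, length.out = 3), l1_ratio = 1)
  tabs <- syn_tabs_clean
  rn <- evaluate_scaled(tabs$dv, "none", scoring = "mae", grid = g)
  rid <- evaluate_scaled(tabs$dv, "exponential", scoring = "mae", grid = g,
                         params = scaling_params("exponential"))
  expect_equal(rid$mae_mean, rn$mae_mean)
  expect_equal(rid$mape_mean, rn$mape_mean)
})
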