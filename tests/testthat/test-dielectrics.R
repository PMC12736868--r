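test_that("Cole-Cole model reduces to its closed-form limits", {
  flat <- tissue_dielectric("flat", eps_inf = 5, delta_eps = numeric(0),
                            tau = numeric(0), alpha = numeric(0),
                            sigma_static = 0)
  expect_equal(cole_cole_complex_permittivity(flat, 1e4), 5 + 0i)
  expect_equal(cole_cole_complex_permittivity(flat, 2.5e5), 5 + 0i)

  cond <- tissue_dielectric("cond", eps_inf = 1, delta_eps = numeric(0),
                            tau = numeric(0), alpha = numeric(0),
                            sigma_static = 0.5)
  f <- 5e4
  expect_equal(cole_cole_complex_permittivity(cond, f),
               complex(real = 1,
                       imaginary = -0.5 / (2 * pi * f * EPS0)))

  expect_error(cole_cole_complex_permittivity(flat, 0), "frequency")
  expect_error(cole_cole_complex_permittivity(flat, -10), "frequency")
})

test_that("tissue_dielectric enforces its parameter invariants", {
  expect_error(tissue_dielectric("x", 0.5, 1, 1e-9, 0, 0.1), "eps_inf")
  expect_error(tissue_dielectric("x", 4, 1, -1e-9, 0, 0.1), "tau")
  expect_error(tissue_dielectric("x", 4, 1, 1e-9, 1.0, 0.1), "alpha")
  expect_error(tissue_dielectric("x", 4, 1, 1e-9, 0, -0.1), "sigma")
})

test_that("shipped parameters match an independent term-by-term evaluation", {
  # brute-force oracle written against the published closed form, summing
  # dispersion terms one at a time with explicit complex arithmetic
  oracle <- function(t, f) {
    w <- 2 * pi * f
    acc <- complex(real = t$eps_inf, imaginary = 0)
    for (n in seq_along(t$delta_eps)) {
      e <- 1 - t$alpha[n]
      mag <- (w * t$tau[n])^e
      jwt <- mag * cos(e * pi / 2) + 1i * mag * sin(e * pi / 2)
      acc <- acc + t$delta_eps[n] / (1 + jwt)
    }
    acc - 1i * t$sigma_static / (w * EPS0)
  }
  freqs <- sweep_grid()$frequencies_hz
  for (name in c("muscle", "fat_infiltrated", "skin_dry", "bladder_urine",
                 "electrode_gel")) {
    t <- tissue_table(name)
    for (f in freqs) {
      got <- cole_cole_complex_permittivity(t, f)
      want <- oracle(t, f)
      expect_lt(Mod(got - want) / Mod(want), 1e-12)
      expect_gt(Re(got), 0)
      if (t$sigma_static > 0) expect_lt(Im(got), 0)
    }
  }
})

test_that("effective properties convert and round-trip exactly", {
  cond <- tissue_dielectric("cond", 1, numeric(0), numeric(0), numeric(0),
                            0.5)
  p <- effective_properties(cond, 1.23e4)
  expect_equal(p$conductivity, 0.5)
  expect_equal(p$relative_permittivity, 1)

  cond2 <- tissue_dielectric("cond2", 1, numeric(0), numeric(0), numeric(0),
                             1.0)
  expect_equal(effective_properties(cond2, 7e4)$conductivity,
               2 * effective_properties(cond, 7e4)$conductivity)

  # sigma* reconstructed from (sigma, eps_r) equals j w eps0 eps-hat
  for (name in c("muscle", "skin_dry")) {
    t <- tissue_table(name)
    for (f in c(1e4, 5e4, 2.5e5)) {
      w <- 2 * pi * f
      eps <- cole_cole_complex_permittivity(t, f)
      sig_star <- complex_conductivity(t, f)
      expect_lt(Mod(sig_star - 1i * w * EPS0 * eps) / Mod(sig_star), 1e-12)
    }
  }
})

test_that("urine is more conductive than muscle at 50 kHz", {
  su <- effective_properties(tissue_table("bladder_urine"), 5e4)$conductivity
  sm <- effective_properties(tissue_table("muscle"), 5e4)$conductivity
  expect_gt(su, sm)
})

test_that("effective conductivity is non-decreasing over the working band", {
  freqs <- sort(sweep_grid()$frequencies_hz)
  for (name in c("muscle", "fat_infiltrated", "skin_dry", "bladder_urine",
                 "electrode_gel")) {
    sig <- effective_properties(tissue_table(name), freqs)$conductivity
    expect_true(all(diff(sig) >= 0), info = name)
    expect_true(all(sig > 0), info = name)
  }
})

test_that("tissue lookup rejects unknown names and lists valid ones", {
  expect_error(tissue_table("bone"), "bladder_urine.*muscle")
  expect_s3_class(tissue_table("electrode_gel"), "tissue_dielectric")
})
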