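# Shared fixtures: small hyperparameter grids and cached synthetic tables so
# individual test files stay fast. Everything is generated in code under
# fixed seeds.

small_grid <- list(lambda = 10^seq(-7, -2, length.out = 6),
                   l1_ratio = c(0.5, 1))

# a noiseless synthetic sweep (15 virtual patients, 50 kHz)
syn_raw_clean <- synthetic_voltage_table(noise_cv = 0, seed = 3)
syn_tabs_clean <- build_voltage_table(syn_raw_clean)

# the same with 1% multiplicative noise
syn_raw_noisy <- synthetic_voltage_table(noise_cv = 0.01, seed = 3)
syn_tabs_noisy <- build_voltage_table(syn_raw_noisy)

# one coarse forward model shared by the solver tests
solver_anatomy <- build_anatomy(0.975, 0.02, 460)
solver_model <- discretize(solver_anatomy, 50e3, level = 1)
solver_solution <- solve_all_pairs(solver_model)

# plants a reciprocal exponential-law anatomy effect on a flat synthetic
# sweep: every inter-patient difference follows the planted multiplier
plant_exp_law <- function(params, noise_cv = 0, seed = 5) {
  pat <- enumerate_sweep(sweep_grid())$patients
  raw <- synthetic_voltage_table(pat, delta_sens = c(0, 0),
                                 delta_base = c(0, 0),
                                 noise_cv = noise_cv, seed = seed)
  m <- scaling_multiplier(params, raw$waist_m, raw$fat_m)
  fcols <- frame_columns(raw)
  raw[, fcols] <- as.matrix(raw[, fcols]) / m
  raw
}
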