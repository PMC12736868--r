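#!/usr/bin/env Rscript
# Stage 3: baseline volume estimators.
#
# Fits the four baseline models -- patient-specific and generalized elastic
# nets on |delta-V| and VCR features -- under both scoring objectives (MAE,
# MAPE), with the full 25 x 10 hyperparameter grid, and writes the
# cross-validation report table (errors, feature counts, neighbor-set usage,
# Jaccard and stability) plus the chosen hyperparameters.
#
# Inputs:  results/voltages_50khz.csv (from 01_simulate.R)
# Outputs: results/model_reports.csv

library(bladdersim)

raw <- read.csv("results/voltages_50khz.csv")
tabs <- build_voltage_table(raw)

rows <- list()
fits <- list()
for (sig in c("dv", "vcr")) {
  for (sc in c("mae", "mape")) {
    for (scope in c("patient_specific", "generalized")) {
      message(sprintf("fitting %s / %s / %s", sig, scope, sc))
      fit <- if (scope == "patient_specific") {
        fit_patient_specific(tabs[[sig]], sc)
      } else {
        fit_generalized(tabs[[sig]], sc)
      }
      fits[[paste(sig, sc, scope)]] <- fit
      r <- model_report(fit)
      rows[[length(rows) + 1]] <- data.frame(
        signal = sig, scope = scope, scoring = sc,
        lambda = r$lambda, l1_ratio = r$l1_ratio,
        mae_mean = r$mae_mean, mae_sd = r$mae_sd,
        mape_mean = r$mape_mean, mape_sd = r$mape_sd,
        n_features_mean = r$n_features_mean,
        n_features_sd = r$n_features_sd,
        f_n = r$f_n, jaccard = r$jaccard, stability = r$stability)
      print(r)
    }
  }
}
reports <- do.call(rbind, rows)
write.csv(reports, "results/model_reports.csv", row.names = FALSE)
saveRDS(fits, "scratch_fits.rds")  # large; consumed by 04_scaling.R
message("wrote results/model_reports.csv")
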