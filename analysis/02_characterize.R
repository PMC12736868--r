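#!/usr/bin/env Rscript
# Stage 2: signal characterization.
#
# Derives |delta-V| and VCR tables from the simulated voltages, summarizes
# their envelopes at maximal bladder volume per waist, fat and frequency,
# computes the pooled Pearson correlations against each parameter, and
# prints the analog-front-end resolution implied by the weakest mean signal.
#
# Inputs:  results/voltages_multifreq.csv (from 01_simulate.R)
# Outputs: results/envelopes.csv, results/pcc.csv

library(bladdersim)

raw <- read.csv("results/voltages_multifreq.csv")
tabs <- build_voltage_table(raw)

envs <- list()
pccs <- list()
for (sig in c("dv", "vcr")) {
  tab50 <- tabs[[sig]][tabs[[sig]]$frequency_hz == 50e3, ]
  for (par in c("waist", "fat")) {
    e <- signal_envelope(tab50, par)
    e$signal <- sig
    e$parameter <- par
    names(e)[1] <- "group"
    envs[[paste(sig, par)]] <- e
    pccs[[paste(sig, par)]] <- data.frame(
      signal = sig, parameter = par, pcc = aggregated_pcc(tab50, par))
  }
  e <- signal_envelope(tabs[[sig]], "frequency")
  e$signal <- sig
  e$parameter <- "frequency"
  names(e)[1] <- "group"
  envs[[paste(sig, "frequency")]] <- e
  pccs[[paste(sig, "frequency")]] <- data.frame(
    signal = sig, parameter = "frequency",
    pcc = aggregated_pcc(tabs[[sig]], "frequency"))
}
envelopes <- do.call(rbind, envs)
pcc_tab <- do.call(rbind, pccs)
write.csv(envelopes, "results/envelopes.csv", row.names = FALSE)
write.csv(pcc_tab, "results/pcc.csv", row.names = FALSE)

message("pooled correlations at maximal bladder volume:")
print(pcc_tab, row.names = FALSE)

env_w <- envelopes[envelopes$signal == "dv" &
                     envelopes$parameter == "waist", ]
weakest <- 1e3 * min(env_w$mean)   # mV, largest waist
message(sprintf(
  "weakest mean |dV| at 460 mL: %.3f mV -> AFE step for 10 mL: %.2f uV",
  weakest, afe_required_step(weakest, 460, 10)))
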