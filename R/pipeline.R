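# End-to-end orchestration: simulate (or accept) a voltage table, derive
# signals, characterize envelopes and correlations, fit the four baseline
# estimators under both scoring objectives, and evaluate the scaled
# generalized models. Every artifact is written as plain CSV alongside the
# run configuration, and identical (config, seed) runs produce identical
# outputs.

#' Run the full analysis pipeline
#'
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @param grid a [sweep_grid()].
#' @param level mesh resolution level for the forward sweep.
#' @param sweep_frequencies frequencies to simulate.
#' @param sweep_volumes volumes to simulate (must include the baseline).
#' @param raw_table optional precomputed raw voltage table (e.g. from
#'   [synthetic_voltage_table()] or an external device in the same schema);
#'   skips the forward sweep.
#' @param working_frequency frequency slice used by the estimators.
#' @param hyper_grid elastic-net hyperparameter grid.
#' @param scorings scoring objectives to fit.
#' @param do_models fit the four baseline models.
#' @param do_scaling evaluate linear/exponential scaled generalized models.
#' @param seed RNG seed (recorded; stages derive their state from it).
#' @param verbose progress messages.
#' @return invisible list with every intermediate artifact.
#' @export
run_pipeline <- function(out_dir = NULL,
                         grid = sweep_grid(),
                         level = 1,
                         sweep_frequencies = 50e3,
                         sweep_volumes = grid$volumes_ml,
                         raw_table = NULL,
                         working_frequency = sweep_frequencies[1],
                         hyper_grid = default_hyper_grid(),
                         scorings = c("mae", "mape"),
                         do_models = TRUE,
                         do_scaling = FALSE,
                         seed = 1,
                         verbose = FALSE) {
  set.seed(seed)
  say <- function(...) if (verbose) message(sprintf(...))

  sweep <- enumerate_sweep(grid)
  say("retained %d virtual patients", nrow(sweep$patients))
  if (is.null(raw_table)) {
    say("running forward sweep (level %d, %d frequencies, %d volumes)",
        level, length(sweep_frequencies), length(sweep_volumes))
    raw_table <- simulate_sweep(grid, level = level,
                                frequencies_hz = sweep_frequencies,
                                volumes_ml = sweep_volumes,
                                verbose = verbose)
  }
  tables <- build_voltage_table(raw_table, grid$baseline_ml)

  envelopes <- list()
  pccs <- list()
  for (sig in c("dv", "vcr")) {
    tab <- tables[[sig]]
    for (par in c("waist", "fat", "frequency")) {
      gcol <- switch(par, waist = "waist_m", fat = "fat_m",
                     frequency = "frequency_hz")
      if (length(unique(tab[[gcol]])) < 2) next
      env <- signal_envelope(tab, par)
      env$signal <- sig
      envelopes[[paste(sig, par)]] <- env
      pccs[[length(pccs) + 1]] <- data.frame(
        signal = sig, parameter = par,
        pcc = aggregated_pcc(tab, par))
    }
  }
  pccs <- if (length(pccs)) do.call(rbind, pccs) else NULL

  reports <- list()
  fits <- list()
  if (do_models) {
    for (sig in c("dv", "vcr")) {
      for (sc in scorings) {
        say("fitting patient-specific %s model (%s)", sig, sc)
        fp <- fit_patient_specific(tables[[sig]], sc, hyper_grid,
                                   working_frequency)
        say("fitting generalized %s model (%s)", sig, sc)
        fg <- fit_generalized(tables[[sig]], sc, hyper_grid,
                              working_frequency)
        fits[[paste(sig, sc, "ps")]] <- fp
        fits[[paste(sig, sc, "gen")]] <- fg
        for (f in list(fp, fg)) {
          r <- model_report(f)
          reports[[length(reports) + 1]] <- data.frame(
            signal = sig, scope = f$model, scoring = sc,
            lambda = r$lambda, l1_ratio = r$l1_ratio,
            mae_mean = r$mae_mean, mae_sd = r$mae_sd,
            mape_mean = r$mape_mean, mape_sd = r$mape_sd,
            n_features_mean = r$n_features_mean,
            n_features_sd = r$n_features_sd,
            f_n = r$f_n, jaccard = r$jaccard, stability = r$stability)
        }
      }
    }
  }
  reports <- if (length(reports)) do.call(rbind, reports) else NULL

  scaled <- list()
  if (do_scaling) {
    for (sig in c("dv", "vcr")) {
      for (sc in scorings) {
        fset <- feature_set_of(fits[[paste(sig, sc, "gen")]])
        for (met in c("linear", "exponential")) {
          say("scaled evaluation: %s / %s / %s", sig, sc, met)
          r <- evaluate_scaled(tables[[sig]], met, fset, sc, hyper_grid,
                               working_frequency)
          scaled[[length(scaled) + 1]] <- data.frame(
            signal = sig, fset = sc, scaling = met,
            mae_mean = r$mae_mean, mae_sd = r$mae_sd,
            mape_mean = r$mape_mean, mape_sd = r$mape_sd)
        }
      }
    }
  }
  scaled <- if (length(scaled)) do.call(rbind, scaled) else NULL

  result <- list(config = list(grid = grid, level = level,
                               sweep_frequencies = sweep_frequencies,
                               sweep_volumes = sweep_volumes,
                               working_frequency = working_frequency,
                               scorings = scorings, seed = seed),
                 patients = sweep$patients,
                 configurations = sweep$configurations,
                 raw = raw_table, tables = tables,
                 envelopes = envelopes, pccs = pccs,
                 model_reports = reports, fits = fits,
                 scaled_reports = scaled)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      if (!is.null(x)) {
        utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
      }
    }
    wr(sweep$patients, "manifest_patients.csv")
    wr(sweep$configurations, "manifest_configurations.csv")
    wr(raw_table, "voltages.csv")
    wr(tables$dv, "signal_dv.csv")
    wr(tables$vcr, "signal_vcr.csv")
    if (length(envelopes)) wr(do.call(rbind, lapply(envelopes, function(e) {
      names(e)[1] <- "group"; e
    })), "envelopes.csv")
    wr(pccs, "pcc.csv")
    wr(reports, "model_reports.csv")
    wr(scaled, "scaled_reports.csv")
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("level: %d", level),
                 sprintf("working_frequency: %g", working_frequency),
                 utils::capture.output(utils::str(grid))),
               file.path(out_dir, "run_config.txt"))
  }
  invisible(result)
}

#' Selected feature set of a fitted model
#'
#' Frame features with nonzero coefficients in any cross-validation fold
#' (the union convention used by the stability score); used to seed the
#' frame-scaling fit.
#'
#' @param fit a `bs_fit`.
#' @return character vector of frame column names (never empty: falls back
#'   to all frames when nothing was selected).
#' @export
feature_set_of <- function(fit) {
  sel <- rownames(fit$coefs)[rowSums(abs(fit$coefs) > COEF_TOL) > 0]
  sel <- intersect(sel, fit$frame_features)
  if (length(sel) == 0) fit$frame_features else sel
}
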