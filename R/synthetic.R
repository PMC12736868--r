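# Parametric synthetic voltage tables.
#
# A fast stand-in for the finite-volume sweep used to exercise the signal,
# estimation, stability and scaling stages: each frame gets a baseline level
# and a linear bladder-volume sensitivity, both attenuated exponentially by
# waist circumference and fat thickness. The default decay rates are
# calibrated so the synthetic signal envelopes shrink with waist and fat by
# factors comparable to the simulation study (|dV| at maximal volume about
# 4.7x smaller from smallest to largest waist, about 1.8x from thinnest to
# thickest fat; VCR attenuated more strongly with fat because the baseline
# voltage grows with fat thickness).

#' Generate a synthetic frame-voltage table
#'
#' @param patients data.frame with `patient_id`, `waist_m`, `fat_m`
#'   (default: the 15 virtual patients retained from the default
#'   [sweep_grid()]).
#' @param volumes_ml bladder volumes, including the 10 mL baseline.
#' @param frequencies_hz frequencies; frame voltages are frequency-flat up
#'   to a small log-frequency tilt (`freq_tilt`).
#' @param informative_frames indices (1..90) of frames that respond to
#'   bladder volume; all others keep their baseline level. Default: all.
#' @param base_range_mv range of per-frame baseline levels (mV) at the
#'   reference anatomy (smallest waist/fat of the default grid).
#' @param sens_range range of per-frame fractional sensitivities: a frame at
#'   full volume is larger than baseline by this fraction at the reference
#'   anatomy.
#' @param delta_sens exponential decay rates (1/m) of the volume-sensitive
#'   signal component in (waist, fat).
#' @param delta_base decay rates (1/m) of the baseline component in
#'   (waist, fat); a negative fat rate makes the baseline grow with fat.
#' @param freq_tilt relative change of voltage per decade of frequency.
#' @param noise_cv multiplicative Gaussian noise coefficient of variation
#'   (0 = noiseless).
#' @param seed RNG seed; tables are reproducible given (arguments, seed).
#' @return data.frame with the [simulate_sweep()] schema.
#' @export
synthetic_voltage_table <- function(patients = NULL,
                                    volumes_ml = c(10, 20, 100, 220, 340, 460),
                                    frequencies_hz = 50e3,
                                    informative_frames = NULL,
                                    base_range_mv = c(0.2, 5),
                                    sens_range = c(0.05, 0.6),
                                    delta_sens = c(3.09, 10.0),
                                    delta_base = c(0.15, -12.2),
                                    freq_tilt = -0.02,
                                    noise_cv = 0,
                                    seed = 1) {
  if (is.null(patients)) patients <- enumerate_sweep(sweep_grid())$patients
  stopifnot(all(c("patient_id", "waist_m", "fat_m") %in% names(patients)))
  frames <- enumerate_frames(6)
  nf <- nrow(frames)
  if (is.null(informative_frames)) informative_frames <- seq_len(nf)

  set.seed(seed)
  base_mv <- exp(stats::runif(nf, log(base_range_mv[1]),
                              log(base_range_mv[2])))
  sens <- stats::runif(nf, sens_range[1], sens_range[2])
  sens[setdiff(seq_len(nf), informative_frames)] <- 0

  w0 <- min(patients$waist_m)
  f0 <- min(patients$fat_m)
  vmax <- max(volumes_ml)
  rows <- list()
  for (p in seq_len(nrow(patients))) {
    aw <- patients$waist_m[p] - w0
    af <- patients$fat_m[p] - f0
    a_b <- exp(-delta_base[1] * aw - delta_base[2] * af)
    a_s <- exp(-delta_sens[1] * aw - delta_sens[2] * af)
    for (vol in volumes_ml) {
      for (fq in frequencies_hz) {
        tilt <- 1 + freq_tilt * log10(fq / 50e3)
        v <- (base_mv * a_b + base_mv * sens * a_s * vol / vmax) *
          tilt * 1e-3
        if (noise_cv > 0) {
          v <- v * (1 + stats::rnorm(nf, 0, noise_cv))
        }
        row <- data.frame(patient_id = patients$patient_id[p],
                          waist_m = patients$waist_m[p],
                          fat_m = patients$fat_m[p],
                          volume_ml = vol, frequency_hz = fq)
        row[frames$frame] <- as.list(abs(v))
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
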