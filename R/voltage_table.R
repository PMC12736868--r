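# Sweep execution: run the forward solver over retained virtual patients,
# volumes and frequencies, producing the raw frame-voltage table that every
# downstream stage consumes.

#' Simulate a parameter sweep
#'
#' Runs [discretize()] + [solve_all_pairs()] for every retained virtual
#' patient, bladder volume and frequency, and returns one row per
#' configuration with the 90 frame-voltage magnitudes as columns. The sparse
#' operator is factorized once per (patient, volume, frequency) and reused
#' across the 15 injections.
#'
#' @param grid a [sweep_grid()].
#' @param level mesh resolution level.
#' @param frequencies_hz frequencies to run (default: all in the grid).
#' @param volumes_ml volumes to run (default: all in the grid; must include
#'   the baseline for downstream signal computation).
#' @param verbose print per-configuration progress.
#' @return data.frame with columns `patient_id`, `waist_m`, `fat_m`,
#'   `volume_ml`, `frequency_hz`, then one column per measurement frame.
#' @export
simulate_sweep <- function(grid, level = 1,
                           frequencies_hz = grid$frequencies_hz,
                           volumes_ml = grid$volumes_ml,
                           verbose = FALSE) {
  sw <- enumerate_sweep(grid)
  frames <- enumerate_frames(6)
  rows <- vector("list", 0)
  for (p in seq_len(nrow(sw$patients))) {
    pat <- sw$patients[p, ]
    for (vol in volumes_ml) {
      a <- build_anatomy(pat$waist_m, pat$fat_m, vol)
      for (f in frequencies_hz) {
        t0 <- Sys.time()
        m <- discretize(a, f, level = level)
        v <- abs(frame_voltages(solve_all_pairs(m, grid$current_a), frames))
        row <- data.frame(patient_id = pat$patient_id,
                          waist_m = pat$waist_m, fat_m = pat$fat_m,
                          volume_ml = vol, frequency_hz = f)
        row[frames$frame] <- as.list(v)
        rows[[length(rows) + 1]] <- row
        if (verbose) {
          message(sprintf("%s V=%g mL f=%g kHz (%.1f s)", pat$patient_id,
                          vol, f / 1e3,
                          as.numeric(Sys.time() - t0, units = "secs")))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Frame metadata columns of a voltage/signal table
#'
#' @param table a table produced by [simulate_sweep()] or
#'   [synthetic_voltage_table()].
#' @return character vector of the frame column names, in enumeration order.
#' @export
frame_columns <- function(table) {
  intersect(enumerate_frames(6)$frame, names(table))
}
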