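# Tetrapolar measurement frames: a current-carrying (CC) electrode pair plus
# a disjoint pick-up (PU) pair. For 6 electrodes: C(6,2) = 15 CC pairs, each
# with C(4,2) = 6 PU pairs, i.e. 90 frames excluding reciprocals.

#' Enumerate tetrapolar measurement frames
#'
#' CC pairs are all unordered electrode pairs in lexicographic order; for
#' each CC pair the PU pairs are all unordered pairs of the remaining
#' electrodes, again lexicographic. Reciprocal frames (CC and PU swapped)
#' both appear — they are distinct injections — but no (cc, pu) combination
#' is listed twice. Frame ids are stable across runs.
#'
#' @param n_electrodes number of electrodes (>= 4).
#' @return data.frame with columns `frame` (id string), `cc1`, `cc2`,
#'   `pu1`, `pu2`, `in_neighbor_set`.
#' @export
enumerate_frames <- function(n_electrodes = 6) {
  if (n_electrodes < 4) stop("need at least 4 electrodes")
  cc <- utils::combn(n_electrodes, 2)
  out <- list()
  for (p in seq_len(ncol(cc))) {
    rest <- setdiff(seq_len(n_electrodes), cc[, p])
    pu <- utils::combn(rest, 2)
    out[[p]] <- data.frame(cc1 = cc[1, p], cc2 = cc[2, p],
                           pu1 = pu[1, ], pu2 = pu[2, ])
  }
  frames <- do.call(rbind, out)
  frames$frame <- sprintf("cc%d%d_pu%d%d",
                          frames$cc1, frames$cc2, frames$pu1, frames$pu2)
  frames$in_neighbor_set <- frames$frame %in%
    neighboring_set(frames)$frame
  frames[, c("frame", "cc1", "cc2", "pu1", "pu2", "in_neighbor_set")]
}

#' The neighboring-method frame set N
#'
#' The conventional EIT addressing scheme restricted to adjacent CC pairs and
#' adjacent PU pairs. Adjacency means consecutive electrode indices along the
#' semicircular arc; by default there is no wrap-around (the belt spans a
#' semicircle, electrodes 1 and n are diametrically opposite, not adjacent).
#'
#' @param frames output of [enumerate_frames()].
#' @param wrap treat the electrode ordering as a closed ring.
#' @return the subset of `frames` in N. For 6 electrodes under arc adjacency
#'   |N| = 12.
#' @export
neighboring_set <- function(frames, wrap = FALSE) {
  n <- max(frames$cc2, frames$pu2)
  adjacent <- function(i, j) {
    abs(i - j) == 1 | (wrap & abs(i - j) == n - 1)
  }
  frames[adjacent(frames$cc1, frames$cc2) &
           adjacent(frames$pu1, frames$pu2), , drop = FALSE]
}

#' Signed voltage change against baseline
#'
#' @param v frame voltage (V).
#' @param v0 baseline frame voltage at the 10 mL bladder volume (V).
#' @return v - v0 (signed; downstream features use the magnitude).
#' @export
delta_v <- function(v, v0) v - v0

#' Voltage change ratio (percent)
#'
#' VCR = |V - V0| / V0 * 100.
#'
#' @inheritParams delta_v
#' @return non-negative percent change.
#' @export
vcr <- function(v, v0) {
  if (any(v0 <= 0)) stop("baseline voltage must be > 0")
  abs(v - v0) / v0 * 100
}

#' Assemble a voltage table from raw solver outputs
#'
#' `raw` holds one row per (patient, volume, frequency) with the 90 frame
#' voltage magnitudes as columns (see [simulate_sweep()]). The 10 mL baseline
#' rows are consumed to form the |delta-V| and VCR feature tables over the
#' non-baseline volumes, and are not emitted as samples.
#'
#' @param raw data.frame with metadata columns `patient_id`, `waist_m`,
#'   `fat_m`, `volume_ml`, `frequency_hz` plus one column per frame.
#' @param baseline_ml baseline bladder volume (default 10 mL).
#' @return list with `voltages` (the input, checked), `dv` (|delta-V|, V) and
#'   `vcr` (%) tables over non-baseline volumes, and `frames`.
#' @export
build_voltage_table <- function(raw, baseline_ml = 10) {
  frames <- enumerate_frames(6)
  fcols <- frames$frame
  missing_cols <- setdiff(fcols, names(raw))
  if (length(missing_cols) > 0) {
    stop("raw table is missing frame columns: ",
         paste(utils::head(missing_cols, 3), collapse = ", "))
  }
  meta <- c("patient_id", "waist_m", "fat_m", "volume_ml", "frequency_hz")
  stopifnot(all(meta %in% names(raw)))
  if (any(as.matrix(raw[, fcols]) <= 0)) {
    stop("all frame-voltage magnitudes must be > 0")
  }

  base <- raw[raw$volume_ml == baseline_ml, , drop = FALSE]
  rest <- raw[raw$volume_ml != baseline_ml, , drop = FALSE]
  key <- function(d) paste(d$patient_id, d$frequency_hz)
  idx <- match(key(rest), key(base))
  if (anyNA(idx)) {
    bad <- rest[which(is.na(idx))[1], ]
    stop(sprintf("missing %g mL baseline row for patient %s at %g Hz",
                 baseline_ml, bad$patient_id, bad$frequency_hz))
  }
  v <- as.matrix(rest[, fcols])
  v0 <- as.matrix(base[idx, fcols])

  dv_tab <- rest
  dv_tab[, fcols] <- abs(delta_v(v, v0))
  vcr_tab <- rest
  vcr_tab[, fcols] <- vcr(v, v0)
  rownames(dv_tab) <- rownames(vcr_tab) <- NULL
  list(voltages = raw, dv = dv_tab, vcr = vcr_tab, frames = frames)
}
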