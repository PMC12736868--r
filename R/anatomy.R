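# Virtual-patient geometry: a 30 cm cylindrical abdomen with a 0.15 cm skin
# shell, a subcutaneous fat shell, muscle interior, and a spherical bladder
# at a fixed anterior offset of one third of the outer radius.

#' Radius of a sphere holding a given bladder volume
#'
#' @param volume_ml bladder volume in mL (> 0).
#' @return sphere radius in metres: (3V / 4 pi)^(1/3) with V in m^3.
#' @export
bladder_radius <- function(volume_ml) {
  if (any(volume_ml <= 0)) stop("bladder volume must be > 0")
  (3 * volume_ml * 1e-6 / (4 * pi))^(1 / 3)
}

#' Default electrode angles (degrees from the anterior midline)
#'
#' Six electrodes on the anterior semicircle at 36 degree spacing; the first
#' and last are diametrically opposite at +/- 90 degrees. The layout is
#' mirror-symmetric about the sagittal (anterior midline) plane.
#' @return numeric vector of 6 angles in degrees.
#' @export
electrode_angles <- function() {
  c(-90, -54, -18, 18, 54, 90)
}

#' Build one virtual-patient anatomy
#'
#' @param waist_m waist circumference in metres (> 0).
#' @param fat_m subcutaneous fat shell thickness in metres (> 0).
#' @param volume_ml bladder volume in mL (> 0).
#' @param skin_m skin thickness in metres (fixed default 0.0015).
#' @param height_m cylinder height in metres (fixed default 0.30).
#' @return an `anatomy` object with derived radii, offsets and electrode
#'   geometry. The anatomy may be geometrically infeasible (bladder
#'   intersecting the fat shell); see [is_feasible()].
#' @export
build_anatomy <- function(waist_m, fat_m, volume_ml,
                          skin_m = 0.0015, height_m = 0.30) {
  if (waist_m <= 0) stop("waist circumference must be > 0")
  if (fat_m <= 0) stop("fat thickness must be > 0")
  r <- waist_m / (2 * pi)
  if (r - skin_m - fat_m <= 0) {
    stop("no muscle region: fat + skin exceed the outer radius")
  }
  a <- structure(list(
    waist_m = waist_m,
    fat_m = fat_m,
    skin_m = skin_m,
    height_m = height_m,
    bladder_volume_ml = volume_ml,
    outer_radius_m = r,
    muscle_radius_m = r - skin_m - fat_m,
    bladder_radius_m = bladder_radius(volume_ml),
    anterior_offset_m = r / 3,
    electrode_angles_deg = electrode_angles(),
    electrode_radius_m = 0.015,
    electrode_thickness_m = 0.005
  ), class = "anatomy")
  a
}

#' @export
print.anatomy <- function(x, ...) {
  cat(sprintf(
    "<anatomy: w = %.3f m, fat = %.3f m, V = %g mL, r = %.4f m, %s>\n",
    x$waist_m, x$fat_m, x$bladder_volume_ml, x$outer_radius_m,
    if (is_feasible(x)) "feasible" else "INFEASIBLE"))
  invisible(x)
}

#' Geometric feasibility of an anatomy
#'
#' A configuration is feasible when the bladder sphere lies entirely inside
#' the muscle region, i.e. it does not breach the subcutaneous fat shell:
#' anterior offset + bladder radius <= outer radius - skin - fat.
#'
#' @param a an `anatomy`.
#' @return logical.
#' @export
is_feasible <- function(a) {
  stopifnot(inherits(a, "anatomy"))
  a$anterior_offset_m + a$bladder_radius_m <= a$muscle_radius_m
}

#' Default sweep grid of the simulation study
#'
#' Six waist circumferences (0.775 to 1.275 m, step 0.10), four fat
#' thicknesses (0.02 to 0.08 m, step 0.02), six bladder volumes
#' (10, 20, 100, 220, 340, 460 mL; 10 mL is the baseline) and nine
#' frequencies spanning 10 to 250 kHz (five steps per decade plus the
#' standard 50 kHz working frequency). Injected current fixed at 1 mA.
#'
#' @param waists_m waist circumferences (m).
#' @param fats_m fat thicknesses (m).
#' @param volumes_ml bladder volumes (mL); must include the baseline.
#' @param frequencies_hz measurement frequencies (Hz).
#' @param current_a injected current (A).
#' @param baseline_ml baseline bladder volume (mL).
#' @return a `sweep_grid` list.
#' @export
sweep_grid <- function(waists_m = seq(0.775, 1.275, by = 0.10),
                       fats_m = seq(0.02, 0.08, by = 0.02),
                       volumes_ml = c(10, 20, 100, 220, 340, 460),
                       frequencies_hz = 1e3 * c(10, 15.8, 25.1, 39.8, 50,
                                                63.1, 100, 158.5, 250),
                       current_a = 1e-3,
                       baseline_ml = 10) {
  stopifnot(length(waists_m) > 0, length(fats_m) > 0,
            length(volumes_ml) > 0, length(frequencies_hz) > 0)
  if (!baseline_ml %in% volumes_ml) {
    stop("volumes_ml must contain the baseline volume")
  }
  structure(list(waists_m = waists_m, fats_m = fats_m,
                 volumes_ml = volumes_ml, frequencies_hz = frequencies_hz,
                 current_a = current_a, baseline_ml = baseline_ml),
            class = "sweep_grid")
}

#' Enumerate the sweep and apply the feasibility filter
#'
#' A (waist, fat) pair is retained as a virtual patient iff it is feasible at
#' the maximum volume of the grid (feasibility is monotone decreasing in
#' volume, so retention at the maximum implies feasibility at every volume).
#' With `per_row = TRUE`, individual (waist, fat, volume) rows are filtered
#' instead and patients keep whatever volumes survive.
#'
#' @param grid a [sweep_grid()].
#' @param per_row filter individual rows instead of whole patients.
#' @return list with `patients` (data.frame: patient_id, waist_m, fat_m and
#'   derived geometry) and `configurations` (data.frame of retained
#'   (patient, volume) rows, one per volume in the grid).
#' @export
enumerate_sweep <- function(grid, per_row = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  combos <- expand.grid(fat_m = grid$fats_m, waist_m = grid$waists_m,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$waist_m, combos$fat_m), c("waist_m", "fat_m")]
  vmax <- max(grid$volumes_ml)
  keep_patient <- vapply(seq_len(nrow(combos)), function(i) {
    a <- build_anatomy(combos$waist_m[i], combos$fat_m[i], vmax)
    is_feasible(a)
  }, logical(1))

  if (per_row) {
    rows <- expand.grid(volume_ml = grid$volumes_ml,
                        fat_m = grid$fats_m, waist_m = grid$waists_m,
                        KEEP.OUT.ATTRS = FALSE)
    feas <- vapply(seq_len(nrow(rows)), function(i) {
      is_feasible(build_anatomy(rows$waist_m[i], rows$fat_m[i],
                                rows$volume_ml[i]))
    }, logical(1))
    rows <- rows[feas, ]
    pk <- unique(rows[, c("waist_m", "fat_m")])
    patients <- pk[order(pk$waist_m, pk$fat_m), ]
  } else {
    patients <- combos[keep_patient, ]
  }
  if (nrow(patients) == 0) stop("no feasible virtual patients in the grid")
  patients$patient_id <- sprintf("P%02d", seq_len(nrow(patients)))
  patients$outer_radius_m <- patients$waist_m / (2 * pi)
  patients$anterior_offset_m <- patients$outer_radius_m / 3
  patients <- patients[, c("patient_id", "waist_m", "fat_m",
                           "outer_radius_m", "anterior_offset_m")]
  rownames(patients) <- NULL

  configurations <- merge(patients,
                          expand.grid(patient_id = patients$patient_id,
                                      volume_ml = grid$volumes_ml,
                                      KEEP.OUT.ATTRS = FALSE,
                                      stringsAsFactors = FALSE),
                          by = "patient_id")
  if (per_row) {
    ok <- vapply(seq_len(nrow(configurations)), function(i) {
      is_feasible(build_anatomy(configurations$waist_m[i],
                                configurations$fat_m[i],
                                configurations$volume_ml[i]))
    }, logical(1))
    configurations <- configurations[ok, ]
  }
  configurations$bladder_radius_m <- bladder_radius(configurations$volume_ml)
  configurations <- configurations[order(configurations$patient_id,
                                         configurations$volume_ml), ]
  rownames(configurations) <- NULL
  list(patients = patients, configurations = configurations)
}
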