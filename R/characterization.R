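# Signal characterization: per-parameter envelopes of the bladder-volume
# signals at maximal simulated volume, pooled Pearson correlations against
# the anatomical parameters, and the analog-front-end resolution worked
# example.

#' Signal envelope grouped by an anatomical parameter
#'
#' Summarizes a |delta-V| or VCR table at the maximal bladder volume: for
#' each level of the grouping parameter, the mean, sample (n-1) standard
#' deviation and quartiles over all frames and remaining conditions.
#'
#' @param signal_table a `dv` or `vcr` table from [build_voltage_table()].
#' @param group_by one of `"waist"`, `"fat"`, `"frequency"`.
#' @return data.frame with columns `group`, `n`, `mean`, `sd`, `q25`,
#'   `median`, `q75`.
#' @export
signal_envelope <- function(signal_table, group_by = c("waist", "fat",
                                                       "frequency")) {
  group_by <- match.arg(group_by)
  gcol <- switch(group_by, waist = "waist_m", fat = "fat_m",
                 frequency = "frequency_hz")
  tab <- signal_table[signal_table$volume_ml == max(signal_table$volume_ml), ]
  vals <- as.matrix(tab[, frame_columns(tab)])
  out <- lapply(sort(unique(tab[[gcol]])), function(g) {
    x <- as.vector(vals[tab[[gcol]] == g, ])
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = stats::sd(x), q25 = q[1], median = q[2], q75 = q[3])
  })
  out <- do.call(rbind, out)
  names(out)[1] <- gcol
  out
}

#' Aggregated Pearson correlation against an anatomical parameter
#'
#' Pools every (row, frame) observation at the maximal bladder volume into a
#' single Pearson correlation against the parameter value. Frequency is
#' correlated on a log10 scale by default (set `log_frequency = FALSE` for
#' linear). With `per_frame = TRUE` the correlation is instead computed per
#' frame and averaged.
#'
#' @inheritParams signal_envelope
#' @param parameter one of `"waist"`, `"fat"`, `"frequency"`.
#' @param log_frequency correlate against log10(frequency).
#' @param per_frame average per-frame correlations instead of pooling.
#' @return Pearson correlation coefficient in [-1, 1].
#' @export
aggregated_pcc <- function(signal_table,
                           parameter = c("waist", "fat", "frequency"),
                           log_frequency = TRUE, per_frame = FALSE) {
  parameter <- match.arg(parameter)
  gcol <- switch(parameter, waist = "waist_m", fat = "fat_m",
                 frequency = "frequency_hz")
  tab <- signal_table[signal_table$volume_ml == max(signal_table$volume_ml), ]
  x <- tab[[gcol]]
  if (parameter == "frequency" && log_frequency) x <- log10(x)
  if (length(unique(x)) < 2) {
    stop(sprintf("parameter '%s' has no variation at maximal volume",
                 parameter))
  }
  vals <- as.matrix(tab[, frame_columns(tab)])
  if (per_frame) {
    r <- apply(vals, 2, function(v) {
      if (stats::sd(v) == 0) stop("zero variance in a frame signal")
      stats::cor(x, v)
    })
    return(mean(r))
  }
  pooled <- as.vector(vals)
  if (stats::sd(pooled) == 0) stop("zero variance in the pooled signal")
  stats::cor(rep(x, times = ncol(vals)), pooled)
}

#' Required analog-front-end voltage resolution
#'
#' Worked example for hardware design: the mean bladder-volume signal at
#' full volume implies the voltage step the front end must resolve to detect
#' a given volume increment, assuming the signal accrues proportionally with
#' volume.
#'
#' @param mean_signal_mv mean |delta-V| at full bladder volume (mV).
#' @param full_volume_ml full bladder volume (mL).
#' @param volume_step_ml target volume resolution (mL), <= full volume.
#' @return required detectable voltage step in microvolts.
#' @export
afe_required_step <- function(mean_signal_mv, full_volume_ml,
                              volume_step_ml) {
  if (any(c(mean_signal_mv, full_volume_ml, volume_step_ml) <= 0)) {
    stop("all inputs must be > 0")
  }
  if (volume_step_ml > full_volume_ml) {
    stop("volume step must not exceed the full volume")
  }
  mean_signal_mv * volume_step_ml / full_volume_ml * 1000
}
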