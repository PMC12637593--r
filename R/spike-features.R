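#' Detect action potentials in a current-clamp sweep
#'
#' An action potential event is a local voltage maximum exceeding
#' `peak_cutoff_mV`, with successive events separated by at least
#' `min_gap_ms` (events are scanned in time order and any candidate
#' closer than the gap to the last accepted event is discarded). The
#' recordings this emulates do not state a detector, so the criterion is
#' deliberately simple and fully configurable.
#'
#' @param sweep A current-clamp [sweep_trace()].
#' @param peak_cutoff_mV Minimum peak voltage (default 0 mV).
#' @param min_gap_ms Refractory gap between accepted peaks (default 1 ms).
#' @return Integer vector of peak sample indices (possibly empty),
#'   ordered by time.
#' @export
detect_aps <- function(sweep, peak_cutoff_mV = 0, min_gap_ms = 1) {
  assert_modality(sweep, "current_clamp")
  v <- sweep$samples
  n <- length(v)
  if (n < 3L) return(integer(0))
  cand <- which(v[2:(n - 1)] > peak_cutoff_mV &
                v[2:(n - 1)] > v[1:(n - 2)] &
                v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  gap <- min_gap_ms / sweep$dt_ms
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= gap) {
      keep <- c(keep, i)
      last <- i
    }
  }
  keep
}

#' Spike threshold by the dV/dt criterion
#'
#' The threshold is the membrane potential at which dV/dt first exceeds
#' 4% of the maximum slope during the upstroke. The upstroke window runs
#' from the preceding interspike minimum (or `window_ms` before the peak
#' for the first spike) to the peak; dV/dt is computed by central
#' differences.
#'
#' @param sweep A current-clamp [sweep_trace()].
#' @param peak_index Sample index of a detected AP peak.
#' @param prev_peak_index Peak index of the preceding AP, or `NULL` for
#'   the first AP.
#' @param frac Slope fraction defining threshold (default 0.04).
#' @param window_ms Pre-peak window used for the first AP (default 2 ms).
#' @return List with `threshold_V_mV`, `threshold_time_ms`,
#'   `max_slope_V_per_s` (mV/ms and V/s coincide numerically).
#' @export
ap_threshold <- function(sweep, peak_index, prev_peak_index = NULL,
                         frac = 0.04, window_ms = 2) {
  assert_modality(sweep, "current_clamp")
  dvdt <- central_slope(sweep$samples, sweep$dt_ms)
  ap_threshold_impl(sweep$samples, dvdt, sweep$dt_ms, peak_index,
                    prev_peak_index, frac, window_ms)
}

ap_threshold_impl <- function(v, dvdt, dt, peak_index,
                              prev_peak_index = NULL, frac = 0.04,
                              window_ms = 2) {
  i0 <- if (is.null(prev_peak_index)) {
    max(1L, peak_index - as.integer(round(window_ms / dt)))
  } else {
    seg <- prev_peak_index:peak_index
    seg[which.min(v[seg])]
  }
  if (i0 >= peak_index) i0 <- max(1L, peak_index - 2L)
  win <- i0:peak_index
  ms <- max(dvdt[win], na.rm = TRUE)
  if (!is.finite(ms) || ms <= 0)
    stop("malformed spike at index ", peak_index,
         ": non-positive maximum upstroke slope")
  cross <- win[which(dvdt[win] > frac * ms)[1]]
  if (is.na(cross))
    stop("malformed spike at index ", peak_index,
         ": no threshold crossing found")
  list(threshold_V_mV = v[cross], threshold_time_ms = (cross - 1) * dt,
       max_slope_V_per_s = ms, threshold_index = cross)
}

# central-difference derivative (mV/ms); NA at the ends
central_slope <- function(v, dt) {
  n <- length(v)
  c(NA_real_, (v[3:n] - v[1:(n - 2)]) / (2 * dt), NA_real_)
}

#' Spike height
#'
#' Height is the peak voltage minus the threshold voltage, both in mV.
#' This threshold-referenced definition is consistent with the reported
#' group means (~85 mV heights with ~-42 mV thresholds imply peaks near
#' +43 mV) and is invariant to a constant offset of the whole trace.
#'
#' @param peak_V_mV Peak voltage (mV).
#' @param threshold_V_mV Threshold voltage (mV); must not exceed the peak.
#' @return Height in mV (>= 0).
#' @export
ap_height <- function(peak_V_mV, threshold_V_mV) {
  if (any(threshold_V_mV > peak_V_mV))
    stop("threshold above peak: malformed spike")
  peak_V_mV - threshold_V_mV
}

#' Spike half-width
#'
#' Width of the spike at the voltage halfway between threshold and peak,
#' using linear interpolation between the bracketing samples of the
#' rising and falling crossings nearest the peak.
#'
#' @param sweep A current-clamp [sweep_trace()].
#' @param peak_index Peak sample index.
#' @param threshold_V_mV Threshold voltage for this spike.
#' @param search_end_index Last sample to search for the falling
#'   crossing (defaults to the next AP's peak or the sweep end).
#' @return Half-width in ms.
#' @export
ap_half_width <- function(sweep, peak_index, threshold_V_mV,
                          search_end_index = NULL) {
  assert_modality(sweep, "current_clamp")
  v <- sweep$samples
  dt <- sweep$dt_ms
  if (is.null(search_end_index)) search_end_index <- length(v)
  v_half <- threshold_V_mV + (v[peak_index] - threshold_V_mV) / 2
  ri <- peak_index
  while (ri > 1L && v[ri - 1L] > v_half) ri <- ri - 1L
  if (ri == 1L && v[1L] > v_half)
    stop("rising half-height crossing not found before spike at index ",
         peak_index)
  t_rise <- (ri - 2) * dt +
    dt * (v_half - v[ri - 1L]) / (v[ri] - v[ri - 1L])
  fi <- peak_index
  while (fi < search_end_index && v[fi + 1L] > v_half) fi <- fi + 1L
  if (fi >= search_end_index)
    stop("falling half-height crossing not found for spike at index ",
         peak_index)
  t_fall <- (fi - 1) * dt +
    dt * (v[fi] - v_half) / (v[fi] - v[fi + 1L])
  t_fall - t_rise
}

#' Interspike potential
#'
#' The most negative membrane potential between two consecutive action
#' potentials (minimum sampled voltage strictly between the two peaks).
#'
#' @param sweep A current-clamp [sweep_trace()].
#' @param peak_index,next_peak_index Peak sample indices of consecutive
#'   APs.
#' @return Minimum voltage (mV) between the peaks.
#' @export
interspike_potential <- function(sweep, peak_index, next_peak_index) {
  assert_modality(sweep, "current_clamp")
  if (next_peak_index <= peak_index + 1L)
    stop("peaks are not consecutive distinct events")
  min(sweep$samples[(peak_index + 1L):(next_peak_index - 1L)])
}

#' Per-spike feature table for one sweep
#'
#' Runs detection and all per-AP extractors, returning one row per
#' detected action potential.
#'
#' @param sweep A current-clamp [sweep_trace()].
#' @param peak_cutoff_mV,min_gap_ms Detection settings ([detect_aps()]).
#' @return A data.frame with columns `ap` (1-based index), `peak_time_ms`,
#'   `peak_V_mV`, `threshold_V_mV`, `threshold_time_ms`, `height_mV`,
#'   `half_width_ms`, `max_slope_V_per_s`, `isi_ms` (interval to the
#'   previous AP; `NA` for the first), `interspike_potential_mV` (most
#'   negative voltage before the next AP; `NA` for the last).
#' @export
ap_events <- function(sweep, peak_cutoff_mV = 0, min_gap_ms = 1) {
  pk <- detect_aps(sweep, peak_cutoff_mV, min_gap_ms)
  n <- length(pk)
  if (n == 0L)
    return(data.frame(ap = integer(0), peak_time_ms = numeric(0),
                      peak_V_mV = numeric(0), threshold_V_mV = numeric(0),
                      threshold_time_ms = numeric(0), height_mV = numeric(0),
                      half_width_ms = numeric(0),
                      max_slope_V_per_s = numeric(0), isi_ms = numeric(0),
                      interspike_potential_mV = numeric(0)))
  dt <- sweep$dt_ms
  dvdt <- central_slope(sweep$samples, dt)
  out <- lapply(seq_len(n), function(j) {
    th <- ap_threshold_impl(sweep$samples, dvdt, dt, pk[j],
                            prev_peak_index = if (j > 1L) pk[j - 1L])
    hw <- ap_half_width(sweep, pk[j], th$threshold_V_mV,
                        search_end_index = if (j < n) pk[j + 1L]
                                           else length(sweep$samples))
    isp <- if (j < n) interspike_potential(sweep, pk[j], pk[j + 1L])
           else NA_real_
    data.frame(ap = j, peak_time_ms = (pk[j] - 1) * dt,
               peak_V_mV = sweep$samples[pk[j]],
               threshold_V_mV = th$threshold_V_mV,
               threshold_time_ms = th$threshold_time_ms,
               height_mV = ap_height(sweep$samples[pk[j]],
                                     th$threshold_V_mV),
               half_width_ms = hw,
               max_slope_V_per_s = th$max_slope_V_per_s,
               isi_ms = if (j > 1L) (pk[j] - pk[j - 1L]) * dt else NA_real_,
               interspike_potential_mV = isp)
  })
  do.call(rbind, out)
}

#' Select the analysis trace and summarise its features
#'
#' To standardise analysis across cells with varying rheobase, scans the
#' cell's current-step sweeps in ascending injected-current order and
#' selects the first containing at least `min_aps` action potentials;
#' metrics are then reported for the 2nd and 10th AP of that trace and as
#' means over the first 10 APs.
#'
#' @param cell A [cell_recording()] with step-protocol current-clamp
#'   sweeps.
#' @param min_aps Minimum AP count for selection (default 10).
#' @param peak_cutoff_mV,min_gap_ms Detection settings.
#' @return A list of class `"trace_summary"`: `sweep_id`, `amplitude_pA`,
#'   `n_APs`, `firing_rate_Hz`, `events` (the [ap_events()] table),
#'   `at_ap2`, `at_ap10` (named metric vectors), `mean10` (means over
#'   APs 1-10).
#' @export
select_trace <- function(cell, min_aps = 10, peak_cutoff_mV = 0,
                         min_gap_ms = 1) {
  stopifnot(inherits(cell, "cell_recording"))
  sweeps <- Filter(function(sw) identical(sw$modality, "current_clamp") &&
                     inherits(sw$stimulus, "step_protocol"), cell$sweeps)
  if (length(sweeps) == 0L)
    stop("cell ", cell$cell_id, " has no current-step sweeps")
  amp <- vapply(sweeps, function(sw) sw$stimulus$amplitude_pA, numeric(1))
  sweeps <- sweeps[order(amp)]
  for (sw in sweeps) {
    ev <- ap_events(sw, peak_cutoff_mV, min_gap_ms)
    if (nrow(ev) >= min_aps) {
      metrics <- c("height_mV", "half_width_ms", "threshold_V_mV",
                   "max_slope_V_per_s", "interspike_potential_mV")
      first10 <- ev[seq_len(min(10L, nrow(ev))), ]
      res <- list(cell_id = cell$cell_id, genotype = cell$genotype,
                  sweep_id = sw$sweep_id,
                  amplitude_pA = sw$stimulus$amplitude_pA,
                  n_APs = nrow(ev),
                  firing_rate_Hz = nrow(ev) /
                    (sw$stimulus$duration_ms / 1000),
                  events = ev,
                  at_ap2 = unlist(ev[2L, metrics]),
                  at_ap10 = if (nrow(ev) >= 10L) unlist(ev[10L, metrics]),
                  mean10 = colMeans(first10[, metrics], na.rm = TRUE))
      class(res) <- "trace_summary"
      return(res)
    }
  }
  stop("cell ", cell$cell_id, " has no sweep with >= ", min_aps,
       " APs; excluded from waveform analysis")
}

#' @export
print.trace_summary <- function(x, ...) {
  cat(sprintf("<trace_summary %s> %s at %g pA: %d APs (%.0f Hz)\n",
              x$cell_id, x$sweep_id, x$amplitude_pA, x$n_APs,
              x$firing_rate_Hz))
  invisible(x)
}
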