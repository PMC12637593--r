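#' Afterhyperpolarization amplitude after a spike train
#'
#' Threshold-to-trough definition: the threshold voltage of the last
#' action potential minus the minimum voltage within `window_ms` after
#' its peak. Positive values mean the membrane hyperpolarises below the
#' last spike threshold. Per-AP and train-average variants can be built
#' from [ap_events()]; the post-train trough is the default reading of a
#' train AHP.
#'
#' @param sweep A current-clamp [sweep_trace()].
#' @param events An [ap_events()] table with at least one AP.
#' @param window_ms Post-train search window (default 50 ms).
#' @return AHP amplitude in mV.
#' @export
ahp_amplitude <- function(sweep, events, window_ms = 50) {
  assert_modality(sweep, "current_clamp")
  if (nrow(events) < 1L) stop("ahp_amplitude needs at least one AP")
  last <- events[nrow(events), ]
  i0 <- as.integer(round(last$peak_time_ms / sweep$dt_ms)) + 1L
  i1 <- i0 + as.integer(round(window_ms / sweep$dt_ms))
  if (i1 > length(sweep$samples)) {
    warning("AHP window truncated at sweep end")
    i1 <- length(sweep$samples)
  }
  last$threshold_V_mV - min(sweep$samples[i0:i1])
}

#' Sag voltage on a hyperpolarizing step
#'
#' Sag is the depolarizing relaxation during a strong hyperpolarizing
#' current step: the steady-state voltage (mean over the final 20% of
#' the step) minus the early minimum (within the first `min_window_ms`
#' of the step). Sag-expressing traces give positive values; a pure RC
#' response gives ~0. Measured on the most hyperpolarizing step of the
#' protocol (-200 pA) by default, and invariant to baseline offset.
#'
#' @param sweep A current-clamp [sweep_trace()] with a step stimulus of
#'   amplitude at most `max_amplitude_pA`.
#' @param min_window_ms Window after step onset searched for the minimum
#'   (default 200 ms).
#' @param max_amplitude_pA Required maximum (most negative allowed is
#'   anything below this; default -120 pA).
#' @return Sag amplitude in mV.
#' @export
sag_voltage <- function(sweep, min_window_ms = 200,
                        max_amplitude_pA = -120) {
  assert_modality(sweep, "current_clamp")
  st <- sweep$stimulus
  if (!inherits(st, "step_protocol") || st$amplitude_pA > max_amplitude_pA)
    stop("sag requires a hyperpolarizing step of at most ",
         max_amplitude_pA, " pA")
  dt <- sweep$dt_ms
  i_on <- as.integer(round(st$onset_ms / dt)) + 1L
  i_off <- as.integer(round((st$onset_ms + st$duration_ms) / dt))
  i_min_end <- i_on + as.integer(round(min_window_ms / dt))
  i_ss_start <- i_off - as.integer(round(0.2 * st$duration_ms / dt))
  if (i_min_end >= i_ss_start)
    stop("step too short for separate minimum and steady-state windows")
  v_min <- min(sweep$samples[i_on:i_min_end])
  v_ss <- mean(sweep$samples[i_ss_start:i_off])
  v_ss - v_min
}

#' Current-voltage and frequency-current tables; rheobase
#'
#' `iv_fi_curves()` computes, per step sweep, the steady-state voltage
#' deflection (mean over the final 20% of the step minus the pre-step
#' baseline) and the firing rate (AP count divided by step duration).
#' `rheobase()` is the smallest step amplitude that elicits at least one
#' action potential.
#'
#' @param cell A [cell_recording()] with step sweeps.
#' @param peak_cutoff_mV,min_gap_ms Detection settings.
#' @return `iv_fi_curves()`: data.frame with `sweep_id`, `amplitude_pA`,
#'   `delta_V_mV`, `n_APs`, `rate_Hz`. `rheobase()`: amplitude in pA
#'   (`NA` if no sweep spikes).
#' @export
iv_fi_curves <- function(cell, peak_cutoff_mV = 0, min_gap_ms = 1) {
  stopifnot(inherits(cell, "cell_recording"))
  sweeps <- Filter(function(sw) identical(sw$modality, "current_clamp") &&
                     inherits(sw$stimulus, "step_protocol"), cell$sweeps)
  if (length(sweeps) == 0L) stop("no current-step sweeps in cell")
  rows <- lapply(sweeps, function(sw) {
    st <- sw$stimulus
    dt <- sw$dt_ms
    i_on <- as.integer(round(st$onset_ms / dt)) + 1L
    i_off <- as.integer(round((st$onset_ms + st$duration_ms) / dt))
    base <- mean(sw$samples[1:max(1L, i_on - 1L)])
    i_ss <- (i_off - as.integer(round(0.2 * st$duration_ms / dt))):i_off
    n_aps <- length(detect_aps(sw, peak_cutoff_mV, min_gap_ms))
    data.frame(sweep_id = sw$sweep_id, amplitude_pA = st$amplitude_pA,
               delta_V_mV = mean(sw$samples[i_ss]) - base,
               n_APs = n_aps,
               rate_Hz = n_aps / (st$duration_ms / 1000),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$amplitude_pA), ]
}

#' @rdname iv_fi_curves
#' @export
rheobase <- function(cell, peak_cutoff_mV = 0, min_gap_ms = 1) {
  tab <- iv_fi_curves(cell, peak_cutoff_mV, min_gap_ms)
  spiking <- tab$amplitude_pA[tab$n_APs >= 1L]
  if (length(spiking) == 0L) return(NA_real_)
  min(spiking)
}

#' Pool APs across sweeps and bin by firing rate
#'
#' Pools per-AP feature rows across sweeps and cells, assigns each AP the
#' firing rate of its sweep, and forms `n_bins` quantile bins of rate so
#' that bins hold comparable AP counts. Returns per-bin, per-genotype
#' means and SEMs for each waveform metric.
#'
#' @param ap_table Data.frame with columns `genotype`, `rate_Hz` and the
#'   metric columns of [ap_events()]; typically built by
#'   [run_intrinsic_study()] from all sweeps of a cohort.
#' @param n_bins Number of rate bins (default 4).
#' @return List with `bins` (rate ranges and counts) and `table`
#'   (per-bin per-genotype mean and SEM per metric, long format).
#' @export
bin_by_rate <- function(ap_table, n_bins = 4) {
  stopifnot(is.data.frame(ap_table), nrow(ap_table) > 0,
            all(c("genotype", "rate_Hz") %in% names(ap_table)))
  qs <- quantile(ap_table$rate_Hz, probs = seq(0, 1, length.out = n_bins + 1),
                 type = 7)
  qs <- unique(qs)
  if (length(qs) - 1L < n_bins)
    warning("fewer distinct rates than requested bins; bins merged")
  if (length(qs) < 2L) qs <- c(qs - 0.5, qs + 0.5)  # all rates identical
  bin <- cut(ap_table$rate_Hz, breaks = qs, include.lowest = TRUE)
  metrics <- intersect(c("height_mV", "half_width_ms", "threshold_V_mV",
                         "max_slope_V_per_s", "interspike_potential_mV"),
                       names(ap_table))
  rows <- list()
  for (b in levels(bin)) for (g in unique(ap_table$genotype)) {
    sel <- ap_table[bin == b & ap_table$genotype == g, , drop = FALSE]
    if (nrow(sel) == 0L) next
    for (m in metrics) {
      x <- sel[[m]][is.finite(sel[[m]])]
      rows[[length(rows) + 1L]] <-
        data.frame(bin = b, genotype = g, metric = m, n = length(x),
                   mean = mean(x), sem = sd(x) / sqrt(length(x)),
                   stringsAsFactors = FALSE)
    }
  }
  bins <- data.frame(bin = levels(bin),
                     n_APs = as.integer(table(bin)[levels(bin)]))
  list(bins = bins, table = do.call(rbind, rows))
}

#' Within-train adaptation metrics
#'
#' For recordings containing at least 50 action potentials: the change in
#' interspike interval between early and late spikes,
#' `delta_ISI = ISI(49-50) - ISI(2-3)` where `ISI(k-(k+1))` is the
#' interval between the k-th and (k+1)-th AP, and the change in waveform
#' metrics between the 50th and 2nd AP (`AP_50 - AP_2`). Computed on the
#' first sweep containing at least 50 APs, mirroring the >=10-AP trace
#' selection rule.
#'
#' @param cell A [cell_recording()] (or an [ap_events()] table via
#'   `adaptation_from_events()`).
#' @param min_aps Eligibility threshold (default 50).
#' @param peak_cutoff_mV,min_gap_ms Detection settings.
#' @return List with `eligible`, `sweep_id`, `delta_ISI_ms`,
#'   `delta_half_width_ms`, `delta_interspike_mV`.
#' @export
adaptation <- function(cell, min_aps = 50, peak_cutoff_mV = 0,
                       min_gap_ms = 1) {
  stopifnot(inherits(cell, "cell_recording"))
  sweeps <- Filter(function(sw) identical(sw$modality, "current_clamp") &&
                     inherits(sw$stimulus, "step_protocol"), cell$sweeps)
  amp <- vapply(sweeps, function(sw) sw$stimulus$amplitude_pA, numeric(1))
  for (sw in sweeps[order(amp)]) {
    ev <- ap_events(sw, peak_cutoff_mV, min_gap_ms)
    if (nrow(ev) >= min_aps) {
      res <- adaptation_from_events(ev)
      res$sweep_id <- sw$sweep_id
      return(res)
    }
  }
  list(eligible = FALSE, sweep_id = NA_character_,
       delta_ISI_ms = NA_real_, delta_half_width_ms = NA_real_,
       delta_interspike_mV = NA_real_)
}

#' @rdname adaptation
#' @param events An [ap_events()] table with >= 50 rows.
#' @export
adaptation_from_events <- function(events) {
  if (nrow(events) < 50L)
    stop("adaptation metrics require >= 50 APs")
  # isi_ms[k] is the interval preceding AP k, so ISI(2-3) = isi_ms[3]
  list(eligible = TRUE, sweep_id = NA_character_,
       delta_ISI_ms = events$isi_ms[50] - events$isi_ms[3],
       delta_half_width_ms = events$half_width_ms[50] -
         events$half_width_ms[2],
       delta_interspike_mV = events$interspike_potential_mV[50] -
         events$interspike_potential_mV[2])
}
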