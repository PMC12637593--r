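#' Conversion parameters for voltage-clamp conductance analysis
#'
#' Symbols of the current-to-conductance conversion: the cell is held at
#' `V_hold` through a series resistance `R_series`; the measured current
#' splits into a leak term through `R_membrane` reversing at `E_rest`
#' and the synaptic (inhibitory) current reversing at `E_i`. With
#' excitatory conductance assumed zero, the pointwise system is
#' \deqn{I_i(t) = g_i(t) (V(t) - E_i)}
#' \deqn{V(t) = V_{hold} - I(t) R_{series}}
#' \deqn{I(t) = I_i(t) + (V(t) - E_{rest}) / R_{membrane}}
#' which [current_to_conductance()] solves for `g_i(t)`. The defaults
#' `V_hold = -70` mV, `E_rest = -16` mV and `E_i = -2.5` mV are the
#' recording-condition constants of the experiments this emulates
#' (high-chloride cesium internal).
#'
#' @param R_series_MOhm,R_membrane_MOhm Per-cell passive values, MOhm.
#' @param V_hold_mV Holding potential (default -70).
#' @param E_rest_mV Leak reversal (default -16).
#' @param E_i_mV Inhibitory reversal (default -2.5).
#' @return An object of class `"conductance_params"`.
#' @export
conductance_params <- function(R_series_MOhm, R_membrane_MOhm,
                               V_hold_mV = -70, E_rest_mV = -16,
                               E_i_mV = -2.5) {
  if (R_series_MOhm < 0 || R_membrane_MOhm <= 0)
    stop("resistances must be positive (R_series may be 0)")
  structure(list(V_hold_mV = V_hold_mV, E_rest_mV = E_rest_mV,
                 E_i_mV = E_i_mV, R_series_MOhm = R_series_MOhm,
                 R_membrane_MOhm = R_membrane_MOhm),
            class = "conductance_params")
}

#' Passive properties from a voltage-clamp test pulse
#'
#' From the current response to a command step `dV`: the series
#' resistance is `dV` over the peak transient current, the membrane
#' resistance is `dV` over the steady-state current change minus
#' `R_series`, the time constant comes from a log-linear (optionally
#' `nls`-refined) exponential fit of the transient decay, and the
#' capacitance is `C = tau (1/R_series + 1/R_membrane)` (the RC circuit
#' relaxes with `tau = C R_series R_membrane / (R_series + R_membrane)`).
#'
#' @param sweep Voltage-clamp [sweep_trace()] containing the test pulse.
#' @param pulse_meta List with `dV_mV`, `onset_ms`, `duration_ms` (taken
#'   from attribute `test_pulse` if missing).
#' @return A [passive_props()].
#' @export
measure_passive <- function(sweep, pulse_meta = NULL) {
  assert_modality(sweep, "voltage_clamp")
  if (is.null(pulse_meta)) pulse_meta <- attr(sweep, "test_pulse")
  if (is.null(pulse_meta)) stop("no test-pulse metadata supplied")
  dt <- sweep$dt_ms
  i <- sweep$samples
  on <- as.integer(round(pulse_meta$onset_ms / dt)) + 1L
  off <- as.integer(round((pulse_meta$onset_ms + pulse_meta$duration_ms) /
                            dt))
  base <- mean(i[1:max(1L, on - 1L)])
  seg <- i[on:off] - base
  pk_rel <- which.max(abs(seg))
  i_peak <- seg[pk_rel]
  if (abs(i_peak) < 1e-9) stop("no detectable test-pulse transient")
  ss_win <- seg[as.integer(round(0.8 * length(seg))):length(seg)]
  i_ss <- mean(ss_win)
  r_s <- 1000 * pulse_meta$dV_mV / i_peak          # mV / pA -> GOhm -> MOhm
  r_tot <- 1000 * pulse_meta$dV_mV / i_ss
  r_m <- r_tot - r_s
  if (!is.finite(r_m) || r_m > 1e4)
    warning("membrane resistance estimate exceeds 10 GOhm")
  # transient decay fit: log-linear on |I - I_ss|, refined by nls
  fit_idx <- which(abs(seg - i_ss) > 0.05 * abs(i_peak - i_ss))
  fit_idx <- fit_idx[fit_idx > pk_rel & fit_idx < 0.8 * length(seg)]
  if (length(fit_idx) < 5L) stop("too few samples to fit the transient")
  tt <- (fit_idx - pk_rel) * dt
  yy <- abs(seg[fit_idx] - i_ss)
  lf <- lm(log(yy) ~ tt)
  tau <- -1 / coef(lf)[[2]]
  fit <- tryCatch({
    nf <- nls(y ~ a * exp(-t / tau), data = list(y = yy, t = tt),
              start = list(a = exp(coef(lf)[[1]]), tau = tau))
    coef(nf)[["tau"]]
  }, error = function(e) tau)
  tau <- fit
  c_m <- 1000 * tau * (1 / r_s + 1 / r_m)          # ms/MOhm = nF -> pF
  passive_props(R_series_MOhm = r_s, R_membrane_MOhm = r_m, tau_ms = tau,
                C_m_pF = c_m, holding_current_pA = base)
}

#' Measure an evoked IPSC
#'
#' Baseline is the mean current over `[stim - 5, stim - 0.5]` ms; the
#' peak is the extremum of the inward deflection within
#' `[stim + blank, stim + search]` ms (the first `blank` ms are skipped
#' to avoid the stimulus artifact). The amplitude is reported as a
#' positive magnitude and is invariant to a holding-current offset.
#'
#' @param sweep Voltage-clamp [sweep_trace()].
#' @param stim_time_ms Stimulus time (ms).
#' @param search_ms Post-stimulus search window end (default 20 ms).
#' @param blank_ms Post-stimulus blanking (default 0.5 ms).
#' @param baseline_window_ms Pre-stimulus window `[stim - w, stim - 0.5]`
#'   (default 5 ms).
#' @return List of class `"ipsc_event"`: `stim_time_ms`, `baseline_pA`,
#'   `raw_peak_pA`, `amplitude_pA`, `peak_time_ms`.
#' @export
detect_ipsc <- function(sweep, stim_time_ms, search_ms = 20,
                        blank_ms = 0.5, baseline_window_ms = 5) {
  assert_modality(sweep, "voltage_clamp")
  dt <- sweep$dt_ms
  t_ms <- sweep_times(sweep)
  if (stim_time_ms < 0 || stim_time_ms >= sweep_duration(sweep))
    stop("stim_time_ms outside the sweep")
  b_sel <- t_ms >= stim_time_ms - baseline_window_ms &
    t_ms <= stim_time_ms - 0.5
  if (!any(b_sel)) b_sel <- t_ms < stim_time_ms
  baseline <- mean(sweep$samples[b_sel])
  s_sel <- which(t_ms >= stim_time_ms + blank_ms &
                 t_ms <= stim_time_ms + search_ms)
  if (length(s_sel) == 0L)
    stop("stimulus artifact blanking occupies the entire search window")
  pk <- s_sel[which.min(sweep$samples[s_sel])]     # inward = most negative
  structure(list(stim_time_ms = stim_time_ms, baseline_pA = baseline,
                 raw_peak_pA = sweep$samples[pk],
                 amplitude_pA = abs(sweep$samples[pk] - baseline),
                 peak_time_ms = t_ms[pk], peak_index = pk),
            class = "ipsc_event")
}

#' Fit the decay of the first IPSC
#'
#' Baseline-anchored mono-exponential least-squares fit of the first
#' IPSC's decay over `[peak + offset, t_end]`, returning an
#' extrapolation function for the residual current at later times (used
#' to correct overlapping paired-pulse responses). A log-linear fit
#' initialises `nls`; if the refinement fails the log-linear solution is
#' kept.
#'
#' @param sweep Voltage-clamp [sweep_trace()].
#' @param ipsc1 The first IPSC's [detect_ipsc()] event.
#' @param t_end_ms End of the fit window (typically second stimulus time
#'   minus 0.5 ms).
#' @param offset_ms Start of the fit window after the peak (default 1).
#' @param tau_bounds_ms Admissible decay range (default 0.5 to 500 ms).
#' @return List of class `"ipsc_decay_fit"`: `A_fit_pA`, `tau_ms`,
#'   `baseline_pA`, `window_ms`, and `predict(t_ms)` giving the fitted
#'   absolute current at time `t_ms`.
#' @export
fit_first_decay <- function(sweep, ipsc1, t_end_ms, offset_ms = 1,
                            tau_bounds_ms = c(0.5, 500)) {
  assert_modality(sweep, "voltage_clamp")
  t_ms <- sweep_times(sweep)
  sel <- which(t_ms >= ipsc1$peak_time_ms + offset_ms & t_ms <= t_end_ms)
  if (length(sel) < 10L)
    stop("decay fit window [", round(ipsc1$peak_time_ms + offset_ms, 3),
         ", ", t_end_ms, "] ms has fewer than 10 samples")
  tt <- t_ms[sel] - ipsc1$peak_time_ms
  yy <- ipsc1$baseline_pA - sweep$samples[sel]     # positive decaying
  pos <- yy > 0
  if (sum(pos) < 10L) stop("decay fit failed: signal below baseline noise")
  lf <- lm(log(yy[pos]) ~ tt[pos])
  tau <- -1 / coef(lf)[[2]]
  a <- exp(coef(lf)[[1]])
  refined <- tryCatch({
    nf <- nls(y ~ a * exp(-t / tau), data = list(y = yy, t = tt),
              start = list(a = a, tau = tau))
    as.list(coef(nf))
  }, error = function(e) list(a = a, tau = tau))
  a <- refined$a; tau <- refined$tau
  if (!is.finite(tau) || tau < tau_bounds_ms[1] || tau > tau_bounds_ms[2])
    stop("decay fit failed: tau = ", format(tau),
         " ms outside (", tau_bounds_ms[1], ", ", tau_bounds_ms[2], ")")
  base <- ipsc1$baseline_pA
  peak_t <- ipsc1$peak_time_ms
  structure(list(A_fit_pA = a, tau_ms = tau, baseline_pA = base,
                 window_ms = c(peak_t + offset_ms, t_end_ms),
                 predict = function(t_ms)
                   base - a * exp(-(t_ms - peak_t) / tau)),
            class = "ipsc_decay_fit")
}

#' Convert a voltage-clamp current trace to inhibitory conductance
#'
#' Pointwise solution of the three-equation system in
#' [conductance_params()]: the actual membrane voltage is
#' `V(t) = V_hold - I(t) R_series`, the leak current
#' `(V(t) - E_rest) / R_membrane` is removed, and the remaining synaptic
#' current is divided by its driving force `V(t) - E_i`. Downstream
#' conductance amplitudes are taken as peak minus pre-stimulus baseline
#' on the returned trace.
#'
#' @param sweep Voltage-clamp [sweep_trace()] (pA).
#' @param params A [conductance_params()].
#' @param check_windows_ms Optional list of `c(start, end)` windows that
#'   will actually be analysed; ill-conditioning (`|V - E_i| < 1` mV) is
#'   an error only inside these windows (whole sweep if `NULL`).
#' @return A numeric vector of conductances in nS, same length as the
#'   sweep, with attribute `v_mV` (the reconstructed voltage).
#' @export
current_to_conductance <- function(sweep, params,
                                   check_windows_ms = NULL) {
  assert_modality(sweep, "voltage_clamp")
  stopifnot(inherits(params, "conductance_params"))
  i_pA <- sweep$samples
  v <- params$V_hold_mV - i_pA * params$R_series_MOhm / 1000
  drive <- v - params$E_i_mV
  bad <- abs(drive) < 1
  if (any(bad)) {
    t_ms <- sweep_times(sweep)
    flag <- if (is.null(check_windows_ms)) bad else {
      inwin <- rep(FALSE, length(t_ms))
      for (w in check_windows_ms)
        inwin <- inwin | (t_ms >= w[1] & t_ms <= w[2])
      bad & inwin
    }
    if (any(flag))
      stop(sprintf(
        "conductance conversion ill-conditioned: |V - E_i| < 1 mV at t = %.3f ms",
        t_ms[which(flag)[1]]))
  }
  i_leak <- 1000 * (v - params$E_rest_mV) / params$R_membrane_MOhm
  g <- (i_pA - i_leak) / drive
  attr(g, "v_mV") <- v
  g
}

#' Decay-corrected paired-pulse ratio
#'
#' For a paired-pulse sweep: the first IPSC amplitude `A1` is measured
#' directly; the overlap of the second IPSC with the decay of the first
#' is corrected by subtracting the extrapolated residual of the first
#' IPSC ([fit_first_decay()]) from the value at the second peak, so
#' `A2_corrected = |I(peak2) - fit(peak2)|` and `PPR = A2_corrected/A1`.
#' The conductance-domain ratio `PPR_g` applies the identical procedure
#' to the [current_to_conductance()] trace. If the decay fit fails the
#' uncorrected amplitude is used with a warning.
#'
#' @param sweep Voltage-clamp [sweep_trace()] with two stimuli.
#' @param stim_times_ms Length-2 vector of stimulus times; defaults to
#'   the sweep's own `stim_train`.
#' @param params Optional [conductance_params()] for `PPR_g`.
#' @param noise_floor_pA Exclusion threshold for `A1` (default 0: keep
#'   all); pipelines pass 3x the baseline noise SD.
#' @param fit_max_ms Cap on the decay-fit window length after the first
#'   peak (default 50 ms); at long intervals the residual has fully
#'   decayed and fitting baseline noise would be meaningless.
#' @param search_ms,blank_ms As in [detect_ipsc()].
#' @return A one-row data.frame of class `"ppr_result"`: `delta_t_ms`,
#'   `A1_pA`, `A2_raw_pA`, `A2_corrected_pA`, `ppr_i`, `ppr_raw`,
#'   `tau_decay_ms`, and (with `params`) `A1_nS`, `A2_corrected_nS`,
#'   `ppr_g`.
#' @export
ppr <- function(sweep, stim_times_ms = NULL, params = NULL,
                noise_floor_pA = 0, fit_max_ms = 50, search_ms = 20,
                blank_ms = 0.5) {
  assert_modality(sweep, "voltage_clamp")
  if (is.null(stim_times_ms)) {
    if (!inherits(sweep$stimulus, "stim_train"))
      stop("no stimulus train on sweep and none supplied")
    stim_times_ms <- sweep$stimulus$pulse_times_ms
  }
  if (length(stim_times_ms) != 2L)
    stop("ppr requires exactly two stimuli")
  dt_pair <- diff(stim_times_ms)
  search1 <- min(search_ms, dt_pair - blank_ms)

  res_i <- ppr_on_trace(sweep$samples, sweep, stim_times_ms, search1,
                        search_ms, blank_ms, fit_max_ms)
  if (res_i$A1 < noise_floor_pA)
    stop("first IPSC amplitude ", round(res_i$A1, 1),
         " pA below the noise floor; sweep excluded")
  out <- data.frame(delta_t_ms = dt_pair, A1_pA = res_i$A1,
                    A2_raw_pA = res_i$A2_raw,
                    A2_corrected_pA = res_i$A2_corr,
                    ppr_i = res_i$A2_corr / res_i$A1,
                    ppr_raw = res_i$A2_raw / res_i$A1,
                    tau_decay_ms = res_i$tau)
  if (!is.null(params)) {
    wins <- list(c(stim_times_ms[1] - 5, stim_times_ms[2] + search_ms))
    g <- current_to_conductance(sweep, params, check_windows_ms = wins)
    gsw <- sweep_trace(g, sweep$dt_ms, "voltage_clamp",
                       sweep_id = paste0(sweep$sweep_id, "_g"))
    # conductance deflections are positive-going; flip so the shared
    # inward-peak machinery applies, magnitudes are unaffected
    gsw$samples <- -gsw$samples
    res_g <- ppr_on_trace(gsw$samples, gsw, stim_times_ms, search1,
                          search_ms, blank_ms, fit_max_ms)
    out$A1_nS <- res_g$A1
    out$A2_corrected_nS <- res_g$A2_corr
    out$ppr_g <- res_g$A2_corr / res_g$A1
  }
  class(out) <- c("ppr_result", class(out))
  out
}

# shared paired-pulse measurement on one (inward-deflection) trace
ppr_on_trace <- function(samples, sweep, stim_times_ms, search1,
                         search_ms, blank_ms, fit_max_ms = 50) {
  sw <- sweep
  sw$samples <- samples
  e1 <- detect_ipsc(sw, stim_times_ms[1], search_ms = search1,
                    blank_ms = blank_ms)
  e2 <- detect_ipsc(sw, stim_times_ms[2], search_ms = search_ms,
                    blank_ms = blank_ms)
  a2_raw <- abs(sw$samples[e2$peak_index] - e1$baseline_pA)
  t_end <- min(stim_times_ms[2] - 0.5, e1$peak_time_ms + fit_max_ms)
  fit <- tryCatch(
    fit_first_decay(sw, e1, t_end_ms = t_end),
    error = function(e) NULL)
  no_overlap <- stim_times_ms[2] - e1$peak_time_ms > fit_max_ms
  if (is.null(fit)) {
    if (!no_overlap)
      warning("decay fit unavailable; using uncorrected second amplitude")
    a2_corr <- a2_raw
    tau <- NA_real_
  } else {
    resid <- fit$predict(e2$peak_time_ms)
    a2_corr <- abs(sw$samples[e2$peak_index] - resid)
    tau <- fit$tau_ms
  }
  list(A1 = e1$amplitude_pA, A2_raw = a2_raw, A2_corr = a2_corr,
       tau = tau)
}

#' Normalised response to a five-pulse train
#'
#' Per-pulse amplitudes are the inward peaks after each stimulus minus
#' the pre-train baseline, with no correction for the decay of preceding
#' IPSCs (matching the analysis convention this reproduces; overlapping
#' kernels therefore bias later pulses upward, which is documented
#' rather than removed). Amplitudes are normalised to the first pulse.
#'
#' @param sweep Voltage-clamp [sweep_trace()] with a 5-pulse train.
#' @param stim_times_ms Stimulus times (defaults to the sweep's train).
#' @param params Optional [conductance_params()] for the conductance
#'   version.
#' @param search_ms,blank_ms As in [detect_ipsc()].
#' @return Data.frame with `pulse`, `delta_t_ms`, `amplitude_pA`,
#'   `norm_i` and (with `params`) `amplitude_nS`, `norm_g`.
#' @export
train_response <- function(sweep, stim_times_ms = NULL, params = NULL,
                           search_ms = 20, blank_ms = 0.5) {
  assert_modality(sweep, "voltage_clamp")
  if (is.null(stim_times_ms)) {
    if (!inherits(sweep$stimulus, "stim_train"))
      stop("no stimulus train on sweep and none supplied")
    stim_times_ms <- sweep$stimulus$pulse_times_ms
  }
  n <- length(stim_times_ms)
  isi <- if (n > 1) stim_times_ms[2] - stim_times_ms[1] else NA_real_
  amp_i <- train_amplitudes(sweep$samples, sweep, stim_times_ms,
                            search_ms, blank_ms, isi)
  out <- data.frame(pulse = seq_len(n), delta_t_ms = isi,
                    amplitude_pA = amp_i, norm_i = amp_i / amp_i[1])
  if (!is.null(params)) {
    wins <- list(c(stim_times_ms[1] - 5, max(stim_times_ms) + search_ms))
    g <- current_to_conductance(sweep, params, check_windows_ms = wins)
    amp_g <- train_amplitudes(-g, sweep, stim_times_ms, search_ms,
                              blank_ms, isi)
    out$amplitude_nS <- amp_g
    out$norm_g <- amp_g / amp_g[1]
  }
  out
}

train_amplitudes <- function(samples, sweep, stim_times_ms, search_ms,
                             blank_ms, isi) {
  sw <- sweep
  sw$samples <- samples
  base_ev <- detect_ipsc(sw, stim_times_ms[1], search_ms = 1,
                         blank_ms = 0.5)
  base <- base_ev$baseline_pA
  vapply(seq_along(stim_times_ms), function(k) {
    this_search <- if (!is.na(isi)) min(search_ms, isi - blank_ms)
                   else search_ms
    ev <- detect_ipsc(sw, stim_times_ms[k], search_ms = this_search,
                      blank_ms = blank_ms)
    abs(sw$samples[ev$peak_index] - base)
  }, numeric(1))
}

#' Unitary IPSC amplitude of a pair
#'
#' Mean IPSC amplitude over the single-pulse sweeps recorded shortly
#' after break-in (3-5 repeats in the emulated protocol), in current
#' (nA) and, when conversion parameters are given, conductance (nS).
#'
#' @param sweeps List of single-pulse voltage-clamp sweeps.
#' @param params Optional [conductance_params()].
#' @param search_ms,blank_ms As in [detect_ipsc()].
#' @return List with `amplitude_nA`, `amplitude_nS` (or `NA`), and `n`.
#' @export
unitary_amplitude <- function(sweeps, params = NULL, search_ms = 20,
                              blank_ms = 0.5) {
  if (length(sweeps) == 0L) stop("no usable single-pulse sweeps")
  amps_pA <- numeric(0)
  amps_nS <- numeric(0)
  for (sw in sweeps) {
    st <- sw$stimulus$pulse_times_ms[1]
    ev <- detect_ipsc(sw, st, search_ms, blank_ms)
    amps_pA <- c(amps_pA, ev$amplitude_pA)
    if (!is.null(params)) {
      g <- current_to_conductance(sw, params,
                                  check_windows_ms = list(c(st - 5,
                                                            st + search_ms)))
      gs <- sw; gs$samples <- -g
      evg <- detect_ipsc(gs, st, search_ms, blank_ms)
      amps_nS <- c(amps_nS, evg$amplitude_pA)
    }
  }
  list(amplitude_nA = mean(amps_pA) / 1000,
       amplitude_nS = if (!is.null(params)) mean(amps_nS) else NA_real_,
       n = length(amps_pA))
}
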