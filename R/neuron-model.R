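#' Parameters of the conductance-based fast-spiking neuron
#'
#' Single-compartment model of a fast-spiking cortical interneuron with a
#' leak current, a transient Na current with fast (`h`) and slow (`s`)
#' inactivation, a fast high-threshold K current (Kv3-like, gate `n`),
#' and a delayed-rectifier K current (Kv2-like) split into two channel
#' populations: homomers and heteromers containing a silent modulatory
#' subunit. Both populations share activation kinetics, but the heteromer
#' half-voltages are shifted hyperpolarized: steady-state inactivation by
#' `d_inact_mV` (the 30-40 mV shift reported for silent-subunit
#' heterotetramers) and activation by `d_act_mV`. `f_het` is the fraction
#' of the total Kv2-like conductance assembled as heteromers; a full
#' knockout of the silent subunit corresponds to `f_het = 0`.
#'
#' Units: voltages mV, conductances nS, capacitance pF, times ms.
#' Defaults were calibrated once so that the wild-type cell (f_het = 0.5)
#' rests near -75 mV with ~75 MOhm input resistance and fires narrow
#' (~0.2 ms half-width), large (~85 mV) action potentials at rates up to
#' ~250 Hz without depolarisation block, and so that removing the
#' heteromer fraction reproduces the expected effect directions on the
#' spike waveform (see the package vignette).
#'
#' @param f_het Heteromer fraction of the Kv2-like conductance, between
#'   0 and 1.
#' @param d_inact_mV Heteromer inactivation half-voltage shift (mV,
#'   negative; default -40, within the reported 30-40 mV range).
#' @param d_act_mV Heteromer activation half-voltage shift (mV, negative).
#' @param cm_pF,g_leak_nS,e_leak_mV Passive membrane parameters.
#' @param g_na_nS,e_na_mV Na conductance and reversal.
#' @param g_kv3_nS,g_kv2_nS,e_k_mV K conductances and reversal.
#' @param noise_sd_pA Stationary SD of the Ornstein-Uhlenbeck background
#'   current noise (pA); 0 disables noise.
#' @param tau_noise_ms Correlation time of the noise current.
#' @param v_init_mV Initial voltage (gates start at steady state).
#' @param ... Gating-kinetics overrides (advanced; see the model source
#'   for the full named set, e.g. `m_vhalf`, `h_tau0`, `z_tau`).
#' @return A named numeric vector of class `"fs_neuron_params"`.
#' @examples
#' p <- fs_neuron_params(f_het = 0)   # silent-subunit knockout cell
#' p[["g_kv2_nS"]]
#' @export
fs_neuron_params <- function(f_het = 0.5, d_inact_mV = -40, d_act_mV = -20,
                             cm_pF = 90, g_leak_nS = 13, e_leak_mV = -75,
                             g_na_nS = 10000, e_na_mV = 68,
                             g_kv3_nS = 1400, g_kv2_nS = 1000,
                             e_k_mV = -80, noise_sd_pA = 20,
                             tau_noise_ms = 1, v_init_mV = -75, ...) {
  par <- c(cm_pF = cm_pF, g_leak_nS = g_leak_nS, e_leak_mV = e_leak_mV,
           g_na_nS = g_na_nS, e_na_mV = e_na_mV,
           m_vhalf = -34, m_k = 8, m_tau = 0.015,
           h_vhalf = -52, h_k = 6,
           h_tau0 = 0.2, h_tau_amp = 0.6, h_tau_vmid = -55,
           h_tau_width = 12,
           s_vhalf = -63, s_k = 4, s_tau = 35, s_min = 0.5,
           g_kv3_nS = g_kv3_nS, e_k_mV = e_k_mV,
           n_vhalf = -8, n_k = 8,
           n_tau0 = 0.08, n_tau_amp = 0.25, n_tau_vmid = -50,
           n_tau_width = 18,
           g_kv2_nS = g_kv2_nS,
           p_vhalf = -20, p_k = 5, p_tau = 0.6,
           z_vhalf = -30, z_k = 7, z_tau = 4, z_min = 0.15,
           f_het = f_het, d_inact_mV = d_inact_mV, d_act_mV = d_act_mV,
           v_init_mV = v_init_mV, noise_sd_pA = noise_sd_pA,
           tau_noise_ms = tau_noise_ms)
  extra <- c(...)
  if (length(extra)) {
    unknown <- setdiff(names(extra), names(par))
    if (length(unknown))
      stop("unknown fs_neuron_params fields: ",
           paste(unknown, collapse = ", "))
    par[names(extra)] <- extra
  }
  if (par[["f_het"]] < 0 || par[["f_het"]] > 1)
    stop("f_het must lie in [0, 1]")
  gs <- c("g_leak_nS", "g_na_nS", "g_kv3_nS", "g_kv2_nS")
  if (any(par[gs] < 0)) stop("conductances must be non-negative")
  if (par[["d_inact_mV"]] > 0)
    stop("d_inact_mV must be a (negative) hyperpolarizing shift")
  structure(par, class = "fs_neuron_params")
}

#' Simulate a current-clamp sweep from the fast-spiking neuron model
#'
#' Integrates the model under a rectangular current step and returns the
#' voltage trace as a current-clamp [sweep_trace()]. Gates and the
#' conductance-form voltage equation are advanced by exponential Euler at
#' an internal sub-step of at most `max_substep_ms`; the scheme is
#' unconditionally stable and spike times change by less than 1% when the
#' sub-step is halved. Background noise is an Ornstein-Uhlenbeck current
#' driven by R's RNG, so results are reproducible given `seed`.
#'
#' @param params An [fs_neuron_params()] vector.
#' @param protocol A [step_protocol()].
#' @param dt_ms Sampling interval of the returned sweep; at most 0.05 ms
#'   (50 kHz or finer, matching the acquisition this emulates).
#' @param total_ms Sweep length; defaults to protocol end + 100 ms.
#' @param seed Optional integer seed applied to R's RNG for the noise
#'   current. Ignored when `noise_sd_pA` is 0.
#' @param sweep_id Identifier for the returned sweep.
#' @param max_substep_ms Upper bound on the integration sub-step (ms).
#' @param record_currents If `TRUE`, attach the total ionic current and
#'   the noise current at sample points as attributes `i_ion_pA` and
#'   `i_noise_pA` (used to verify charge conservation).
#' @return A current-clamp [sweep_trace()].
#' @examples
#' sw <- simulate_fs_neuron(fs_neuron_params(noise_sd_pA = 0),
#'                          step_protocol(600), dt_ms = 0.02)
#' range(sw$samples)
#' @export
simulate_fs_neuron <- function(params, protocol, dt_ms = 0.02,
                               total_ms = NULL, seed = NULL,
                               sweep_id = "sweep_1",
                               max_substep_ms = 0.005,
                               record_currents = FALSE) {
  stopifnot(inherits(params, "fs_neuron_params"),
            inherits(protocol, "step_protocol"))
  if (dt_ms > 0.05)
    stop("dt_ms must be <= 0.05 ms (50 kHz or finer)")
  if (is.null(total_ms))
    total_ms <- protocol$onset_ms + protocol$duration_ms + 100
  n <- as.integer(round(total_ms / dt_ms))
  if (protocol$onset_ms + protocol$duration_ms > total_ms)
    stop("protocol does not fit within the sweep")
  t_ms <- (seq_len(n) - 1) * dt_ms
  i_stim <- ifelse(t_ms >= protocol$onset_ms &
                   t_ms < protocol$onset_ms + protocol$duration_ms,
                   protocol$amplitude_pA, 0)
  n_sub <- max(1L, as.integer(ceiling(dt_ms / max_substep_ms)))
  noise_z <- if (params[["noise_sd_pA"]] > 0) {
    if (!is.null(seed)) set.seed(seed)
    rnorm(n * n_sub)
  } else numeric(0)
  r <- .fs_neuron_sim(unclass(params), dt_ms, n, n_sub, i_stim, noise_z,
                      record_currents)
  sw <- sweep_trace(r$v_mV, dt_ms = dt_ms, modality = "current_clamp",
                    stimulus = protocol, sweep_id = sweep_id)
  if (record_currents) {
    attr(sw, "i_ion_pA") <- r$i_ion_pA
    attr(sw, "i_noise_pA") <- r$i_noise_pA
    attr(sw, "i_stim_pA") <- i_stim
  }
  sw
}
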