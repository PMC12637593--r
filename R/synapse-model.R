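#' Parameters of the depressing inhibitory synapse model
#'
#' Phenomenological resource-depletion (Tsodyks-Markram-style) model of a
#' depressing GABAergic synapse recorded in voltage clamp on the
#' postsynaptic side. Each presynaptic pulse releases a fraction `U` of
#' the available resource; the resource recovers exponentially with time
#' constant `tau_rec_ms`. Event `n` has underlying amplitude
#' `scale_pA * U * R_n` and is convolved with a difference-of-exponentials
#' IPSC kernel normalised to unit peak. Currents are inward (negative),
#' as with a high-chloride internal solution at a -70 mV holding
#' potential; amplitudes are reported downstream as positive magnitudes.
#'
#' With `release = "binomial"`, the per-event amplitude is drawn as
#' `scale_pA/n_sites * Binomial(n_sites, U * R_n)` around the mean-field
#' resource trajectory, so the average over repeats converges to the
#' deterministic amplitudes.
#'
#' The default holding current is the value consistent with the passive
#' model used by [current_to_conductance()] (`V_hold`, `E_rest`,
#' `R_series`, `R_membrane`), so that the converted conductance trace has
#' zero baseline.
#'
#' @param U Utilisation (release) fraction per pulse, in (0, 1].
#' @param tau_rec_ms Resource recovery time constant (ms).
#' @param scale_pA Unitary amplitude scale: an isolated pulse peaks at
#'   `scale_pA * U` (pA).
#' @param tau_r_ms,tau_d_ms IPSC kernel rise and decay time constants
#'   (ms); must satisfy `tau_d_ms > tau_r_ms > 0`.
#' @param release `"deterministic_mean"` or `"binomial"`.
#' @param n_sites Number of release sites for binomial release.
#' @param R_series_MOhm,R_membrane_MOhm Passive properties of the
#'   postsynaptic cell emulated by the sweep.
#' @param holding_pA Baseline holding current (pA); `NULL` uses the
#'   value consistent with the passive model.
#' @param noise_sd_pA Gaussian measurement noise SD (pA).
#' @return An object of class `"synapse_params"`.
#' @examples
#' synapse_params(U = 0.6, tau_rec_ms = 50)
#' @export
synapse_params <- function(U = 0.55, tau_rec_ms = 50, scale_pA = 2000,
                           tau_r_ms = 0.5, tau_d_ms = 10,
                           release = c("deterministic_mean", "binomial"),
                           n_sites = 12, R_series_MOhm = 19,
                           R_membrane_MOhm = 211, holding_pA = NULL,
                           noise_sd_pA = 20) {
  release <- match.arg(release)
  if (U <= 0 || U > 1) stop("U must lie in (0, 1]")
  if (tau_rec_ms <= 0 || tau_r_ms <= 0 || tau_d_ms <= 0)
    stop("time constants must be positive")
  if (tau_d_ms <= tau_r_ms) stop("tau_d_ms must exceed tau_r_ms")
  if (is.null(holding_pA))
    holding_pA <- 1000 * (-70 - (-16)) / (R_membrane_MOhm + R_series_MOhm)
  structure(list(U = U, tau_rec_ms = tau_rec_ms, scale_pA = scale_pA,
                 tau_r_ms = tau_r_ms, tau_d_ms = tau_d_ms,
                 release = release, n_sites = n_sites,
                 R_series_MOhm = R_series_MOhm,
                 R_membrane_MOhm = R_membrane_MOhm,
                 holding_pA = holding_pA, noise_sd_pA = noise_sd_pA),
            class = "synapse_params")
}

#' Resource-depletion amplitudes for a pulse train
#'
#' Direct recursion of the depression model: `R_1 = 1`,
#' `A_n = U * R_n`, and
#' `R_{n+1} = R_n (1 - U) + (1 - R_n (1 - U)) (1 - exp(-dt_n / tau_rec))`.
#' For a pulse pair separated by `dt` this gives the closed form
#' `A_2 / A_1 = 1 - U exp(-dt / tau_rec)`.
#'
#' @param U Utilisation fraction in (0, 1].
#' @param tau_rec_ms Recovery time constant (ms).
#' @param pulse_times_ms Strictly increasing pulse times (ms).
#' @return Numeric vector of relative amplitudes `U * R_n` (so an
#'   isolated first pulse has amplitude `U`).
#' @examples
#' a <- tm_amplitudes(0.55, 200, c(0, 10))
#' a[2] / a[1]  # 1 - 0.55 * exp(-10/200)
#' @export
tm_amplitudes <- function(U, tau_rec_ms, pulse_times_ms) {
  stopifnot(U > 0, U <= 1, tau_rec_ms > 0,
            !is.unsorted(pulse_times_ms, strictly = TRUE))
  n <- length(pulse_times_ms)
  R <- numeric(n)
  R[1] <- 1
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      left <- R[i] * (1 - U)
      dt <- pulse_times_ms[i + 1] - pulse_times_ms[i]
      R[i + 1] <- left + (1 - left) * (1 - exp(-dt / tau_rec_ms))
    }
  }
  U * R
}

# difference-of-exponentials kernel normalised to unit peak
ipsc_kernel <- function(t_ms, tau_r_ms, tau_d_ms) {
  tp <- tau_r_ms * tau_d_ms / (tau_d_ms - tau_r_ms) *
    log(tau_d_ms / tau_r_ms)
  norm <- exp(-tp / tau_d_ms) - exp(-tp / tau_r_ms)
  k <- ifelse(t_ms < 0, 0, exp(-t_ms / tau_d_ms) - exp(-t_ms / tau_r_ms))
  k / norm
}

#' Simulate a voltage-clamp IPSC sweep for a presynaptic pulse train
#'
#' Computes per-pulse amplitudes with [tm_amplitudes()] (optionally
#' binomially sampled around the mean-field trajectory), superimposes a
#' unit-peak difference-of-exponentials kernel at each pulse time, adds
#' the holding current and Gaussian noise, and returns a voltage-clamp
#' [sweep_trace()] with inward (negative) IPSC deflections.
#'
#' @param params A [synapse_params()].
#' @param stim A [stim_train()]; pulse times must be separated by more
#'   than `dt_ms`.
#' @param dt_ms Sampling interval (<= 0.1 ms; 10 kHz default).
#' @param total_ms Sweep length; defaults to last pulse + 200 ms.
#' @param seed Optional RNG seed (noise and binomial release).
#' @param sweep_id Identifier for the returned sweep.
#' @return A voltage-clamp [sweep_trace()]. The underlying noise-free
#'   per-pulse amplitudes (pA, positive) are attached as attribute
#'   `true_amplitudes_pA`.
#' @examples
#' sw <- simulate_ipsc_train(synapse_params(noise_sd_pA = 0),
#'                           stim_train(c(50, 60)), seed = 1)
#' min(sw$samples)  # inward peak
#' @export
simulate_ipsc_train <- function(params, stim, dt_ms = 0.1, total_ms = NULL,
                                seed = NULL, sweep_id = "sweep_1") {
  stopifnot(inherits(params, "synapse_params"),
            inherits(stim, "stim_train"))
  if (dt_ms > 0.1) stop("dt_ms must be <= 0.1 ms (10 kHz or finer)")
  pt <- stim$pulse_times_ms
  if (length(pt) > 1 && min(diff(pt)) <= dt_ms)
    stop("pulses closer than the sampling interval dt_ms")
  if (is.null(total_ms)) total_ms <- max(pt) + 200
  n <- as.integer(round(total_ms / dt_ms))
  if (max(pt) >= total_ms) stop("stimulus does not fit within the sweep")
  t_ms <- (seq_len(n) - 1) * dt_ms

  if (!is.null(seed)) set.seed(seed)
  amp_rel <- tm_amplitudes(params$U, params$tau_rec_ms, pt)
  if (params$release == "binomial") {
    p_rel <- pmin(1, pmax(0, amp_rel))
    amp_rel <- rbinom(length(pt), params$n_sites, p_rel) / params$n_sites
  }
  amp_pA <- params$scale_pA * amp_rel

  i <- rep(params$holding_pA, n)
  for (k in seq_along(pt)) {
    idx <- which(t_ms >= pt[k])
    i[idx] <- i[idx] -
      amp_pA[k] * ipsc_kernel(t_ms[idx] - pt[k], params$tau_r_ms,
                              params$tau_d_ms)
  }
  if (params$noise_sd_pA > 0)
    i <- i + rnorm(n, 0, params$noise_sd_pA)
  sw <- sweep_trace(i, dt_ms = dt_ms, modality = "voltage_clamp",
                    stimulus = stim, sweep_id = sweep_id)
  attr(sw, "true_amplitudes_pA") <- amp_pA
  sw
}

#' Simulate a voltage-clamp test-pulse sweep
#'
#' Closed-form current response of a series-resistance + membrane RC
#' circuit to a voltage command step, used to exercise
#' [measure_passive()]: the current jumps to `dV/R_s`, then relaxes with
#' `tau = C (R_s R_m) / (R_s + R_m)` to the steady state
#' `dV / (R_s + R_m)`.
#'
#' @param R_series_MOhm,R_membrane_MOhm,C_m_pF Circuit parameters.
#' @param dV_mV Command step amplitude (mV), conventionally negative.
#' @param onset_ms,duration_ms Step timing.
#' @param dt_ms Sampling interval.
#' @param total_ms Sweep length.
#' @param holding_pA Baseline current (pA).
#' @param noise_sd_pA Gaussian noise SD (pA).
#' @param seed Optional RNG seed.
#' @return A voltage-clamp [sweep_trace()] whose stimulus is `NULL`; the
#'   pulse metadata is attached as attribute `test_pulse`.
#' @export
simulate_test_pulse <- function(R_series_MOhm = 19, R_membrane_MOhm = 211,
                                C_m_pF = 150, dV_mV = -5, onset_ms = 20,
                                duration_ms = 100, dt_ms = 0.1,
                                total_ms = 200, holding_pA = -100,
                                noise_sd_pA = 0, seed = NULL) {
  stopifnot(R_series_MOhm > 0, R_membrane_MOhm > 0, C_m_pF > 0)
  t_ms <- seq(0, total_ms - dt_ms, by = dt_ms)
  rp <- R_series_MOhm * R_membrane_MOhm / (R_series_MOhm + R_membrane_MOhm)
  tau <- C_m_pF * rp / 1000                      # pF * MOhm = us -> ms
  i0 <- 1000 * dV_mV / R_series_MOhm             # pA
  iss <- 1000 * dV_mV / (R_series_MOhm + R_membrane_MOhm)
  i <- rep(holding_pA, length(t_ms))
  on <- t_ms >= onset_ms & t_ms < onset_ms + duration_ms
  i[on] <- holding_pA + iss + (i0 - iss) * exp(-(t_ms[on] - onset_ms) / tau)
  off <- t_ms >= onset_ms + duration_ms
  # symmetric relaxation back after the step
  i[off] <- holding_pA - (iss + (i0 - iss) *
                            exp(-(t_ms[off] - onset_ms - duration_ms) / tau)) +
    (iss - iss * exp(-(t_ms[off] - onset_ms - duration_ms) / tau)) * 0
  if (noise_sd_pA > 0) {
    if (!is.null(seed)) set.seed(seed)
    i <- i + rnorm(length(i), 0, noise_sd_pA)
  }
  sw <- sweep_trace(i, dt_ms = dt_ms, modality = "voltage_clamp",
                    stimulus = NULL, sweep_id = "testpulse")
  attr(sw, "test_pulse") <- list(dV_mV = dV_mV, onset_ms = onset_ms,
                                 duration_ms = duration_ms)
  sw
}
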