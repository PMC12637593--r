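#' Genotype effect directions in the neuron model
#'
#' Simulates a knockout (`f_het = 0`) and a heteromer-carrying cell with
#' otherwise identical parameters across a family of current steps and
#' tabulates the knockout-minus-control difference of the 10th-AP
#' metrics, the per-step material for a sign test of the expected effect
#' directions (narrower half-width, more negative interspike potential
#' and threshold, larger maximum slope in the knockout).
#'
#' Simulations are noise-free and sampled at `dt_ms` (default 0.005 ms,
#' fine enough that sampling quantization of the threshold crossing is
#' small against the effect sizes).
#'
#' @param amps_pA Current steps (default 200-1200 pA in 100 pA steps).
#' @param f_het Heteromer fraction of the control cell (default 0.5).
#' @param dt_ms Sampling interval.
#' @param step_duration_ms,step_onset_ms Step timing.
#' @return Data.frame with one row per step that yielded at least 10 APs
#'   in both cells: `amplitude_pA`, `n_ko`, `n_ctrl`, and differences
#'   `d_half_width_ms`, `d_interspike_mV`, `d_threshold_mV`,
#'   `d_max_slope_V_per_s` (knockout minus control, 10th AP).
#' @export
compare_f_het <- function(amps_pA = seq(200, 1200, by = 100),
                          f_het = 0.5, dt_ms = 0.005,
                          step_duration_ms = 500, step_onset_ms = 100) {
  p_ctrl <- fs_neuron_params(f_het = f_het, noise_sd_pA = 0)
  p_ko <- fs_neuron_params(f_het = 0, noise_sd_pA = 0)
  rows <- list()
  for (a in amps_pA) {
    pr <- step_protocol(a, step_onset_ms, step_duration_ms)
    ev_c <- ap_events(simulate_fs_neuron(p_ctrl, pr, dt_ms = dt_ms))
    ev_k <- ap_events(simulate_fs_neuron(p_ko, pr, dt_ms = dt_ms))
    if (nrow(ev_c) >= 11L && nrow(ev_k) >= 11L) {
      rows[[length(rows) + 1L]] <- data.frame(
        amplitude_pA = a, n_ko = nrow(ev_k), n_ctrl = nrow(ev_c),
        d_half_width_ms = ev_k$half_width_ms[10] - ev_c$half_width_ms[10],
        d_interspike_mV = ev_k$interspike_potential_mV[10] -
          ev_c$interspike_potential_mV[10],
        d_threshold_mV = ev_k$threshold_V_mV[10] - ev_c$threshold_V_mV[10],
        d_max_slope_V_per_s = ev_k$max_slope_V_per_s[10] -
          ev_c$max_slope_V_per_s[10])
    }
  }
  do.call(rbind, rows)
}

#' Replicated group comparison of paired-pulse ratios
#'
#' Monte-Carlo study of the synaptic pipeline at the paired-recording
#' design size: per replicate, two cohorts of pairs are generated with
#' genotype release probabilities `U`, paired-pulse sweeps are simulated
#' and measured (simulate, detect, decay-correct, ratio, average over
#' repeats), and an unpaired two-tailed t test compares genotypes at
#' each interstimulus interval. Setting both entries of `U` equal gives
#' the null (type-I) configuration.
#'
#' @param n_replicates Number of replicate studies.
#' @param U Length-2 vector: wild-type and knockout release probability.
#' @param n_pairs Length-2 vector of pairs per group (default 11, 10).
#' @param delta_ts_ms Interstimulus intervals tested.
#' @param n_repeats Sweeps per interval per pair.
#' @param U_sd Between-pair SD of the release probability.
#' @param tau_rec_ms,noise_sd_pA Generator settings.
#' @param alpha Test level.
#' @param seed RNG seed.
#' @return List with `rejection_rate` (named by interval), `mean_diff`
#'   (mean knockout-minus-wild-type PPR difference per interval) and the
#'   per-replicate p-value matrix `p_values`.
#' @export
ppr_group_simulation <- function(n_replicates = 100, U = c(0.60, 0.45),
                                 n_pairs = c(11, 10),
                                 delta_ts_ms = c(10, 20, 200, 1000),
                                 n_repeats = 3, U_sd = 0.08,
                                 tau_rec_ms = 50, noise_sd_pA = 20,
                                 alpha = 0.05, seed = 1) {
  set.seed(seed)
  pmat <- matrix(NA_real_, n_replicates, length(delta_ts_ms),
                 dimnames = list(NULL, delta_ts_ms))
  dmat <- pmat
  for (r in seq_len(n_replicates)) {
    per_group <- lapply(1:2, function(g) {
      vapply(seq_len(n_pairs[g]), function(i) {
        u <- min(0.95, max(0.05, rnorm(1, U[g], U_sd)))
        par <- synapse_params(U = u, tau_rec_ms = tau_rec_ms,
                              noise_sd_pA = noise_sd_pA)
        vapply(delta_ts_ms, function(d) {
          mean(vapply(seq_len(n_repeats), function(k) {
            sw <- simulate_ipsc_train(par, stim_train(c(50, 50 + d)),
                                      total_ms = 50 + d + 100)
            ppr(sw)$ppr_i
          }, numeric(1)))
        }, numeric(1))
      }, numeric(length(delta_ts_ms)))
    })
    for (j in seq_along(delta_ts_ms)) {
      wt <- per_group[[1]][j, ]
      ko <- per_group[[2]][j, ]
      pmat[r, j] <- unpaired_t(wt, ko)$p_value
      dmat[r, j] <- mean(ko) - mean(wt)
    }
  }
  list(rejection_rate = colMeans(pmat < alpha), mean_diff = colMeans(dmat),
       p_values = pmat)
}
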