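test_that("passive properties are recovered from an ideal test pulse", {
  sw <- simulate_test_pulse(R_series_MOhm = 19, R_membrane_MOhm = 211,
                            C_m_pF = 150)
  pp <- measure_passive(sw)
  expect_lt(abs(pp$R_series_MOhm - 19) / 19, 0.05)
  expect_lt(abs(pp$R_membrane_MOhm - 211) / 211, 0.05)
  expect_lt(abs(pp$C_m_pF - 150) / 150, 0.05)

  # R_m -> infinity: steady state approaches dV/R_s only, estimate flagged
  sw2 <- simulate_test_pulse(R_series_MOhm = 19, R_membrane_MOhm = 1e7,
                             C_m_pF = 150)
  expect_warning(pp2 <- measure_passive(sw2), "10 GOhm")
  expect_gt(pp2$R_membrane_MOhm, 1e4)

  # doubling dV doubles the currents and leaves resistances unchanged
  sw3 <- simulate_test_pulse(dV_mV = -10)
  pp3 <- measure_passive(sw3)
  expect_equal(pp3$R_series_MOhm, pp$R_series_MOhm, tolerance = 1e-6)
  expect_equal(pp3$R_membrane_MOhm, pp$R_membrane_MOhm, tolerance = 1e-4)
})

test_that("IPSC detection: flat trace, known amplitude, offset invariance", {
  flat <- sweep_trace(rep(-100, 2000), 0.1, "voltage_clamp")
  ev <- detect_ipsc(flat, 100)
  expect_equal(ev$amplitude_pA, 0)

  par <- synapse_params(U = 0.5, scale_pA = 1600, noise_sd_pA = 0)
  sw <- simulate_ipsc_train(par, stim_train(50))
  ev2 <- detect_ipsc(sw, 50)
  expect_equal(ev2$amplitude_pA, 800, tolerance = 1)

  sw_off <- sw; sw_off$samples <- sw$samples - 150
  ev3 <- detect_ipsc(sw_off, 50)
  expect_equal(ev3$amplitude_pA, ev2$amplitude_pA, tolerance = 1e-9)

  expect_error(detect_ipsc(sw, 50, search_ms = 0.4), "artifact")
})

test_that("decay fit recovers a pure exponential and extrapolates", {
  dt <- 0.1
  t <- seq(0, 200 - dt, by = dt)
  base <- -100
  a1 <- 900
  i <- base - ifelse(t < 50, 0, a1 * exp(-(t - 50) / 10))
  sw <- sweep_trace(i, dt, "voltage_clamp")
  ev <- detect_ipsc(sw, 49.4)   # peak lands at t = 50
  fit <- fit_first_decay(sw, ev, t_end_ms = 90)
  expect_lt(abs(fit$tau_ms - 10) / 10, 0.01)
  # extrapolated deflection at peak + tau equals A1/e
  resid <- ev$baseline_pA - fit$predict(ev$peak_time_ms + 10)
  expect_lt(abs(resid - a1 / exp(1)) / (a1 / exp(1)), 0.01)

  # biexponential truth fit mono-exponentially: extrapolation bias at
  # +10 ms stays bounded (model-mismatch quantification)
  i2 <- base - ifelse(t < 50, 0, 450 * (exp(-(t - 50) / 5) +
                                          exp(-(t - 50) / 50)))
  sw2 <- sweep_trace(i2, dt, "voltage_clamp")
  ev2 <- detect_ipsc(sw2, 49.4)
  fit2 <- fit_first_decay(sw2, ev2, t_end_ms = 59)  # window [peak+1, 9]
  truth10 <- 450 * (exp(-10 / 5) + exp(-10 / 50))
  est10 <- ev2$baseline_pA - fit2$predict(50 + 10)
  expect_lt(abs(est10 - truth10) / truth10, 0.25)
})

test_that("paired-pulse correction removes the overlap bias", {
  # constructed pair with true A2/A1 = 0.5 and strong overlap
  dt <- 0.1; tau_r <- 0.2; tau_d <- 10
  t <- seq(0, 300 - dt, by = dt)
  kern <- function(tt) ipsc <- ifelse(tt < 0, 0, {
    tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
    nrm <- exp(-tp / tau_d) - exp(-tp / tau_r)
    (exp(-tt / tau_d) - exp(-tt / tau_r)) / nrm
  })
  a1 <- 1000; a2 <- 500; s1 <- 50; s2 <- 60
  i <- -100 - a1 * kern(t - s1) - a2 * kern(t - s2)
  sw <- sweep_trace(i, dt, "voltage_clamp",
                    stimulus = stim_train(c(s1, s2)))
  res <- ppr(sw)
  expect_lt(abs(res$ppr_i - 0.5) / 0.5, 0.02)
  # the uncorrected ratio carries the analytically predicted upward bias
  pk2 <- oracle_kernel_peak(c(a1, a2), c(s1, s2), tau_r, tau_d,
                            from = s2 + 0.3, to = s2 + 20)
  expect_equal(res$ppr_raw, pk2$value / a1, tolerance = 0.02)
  expect_gt(res$ppr_raw, 0.5 + 0.25)   # bias ~ exp(-10/10) ~ 0.37

  # identical kernels fully decayed: PPR -> 1
  i2 <- -100 - a1 * kern(t - 50) - a1 * kern(t - 250)
  sw2 <- sweep_trace(i2, dt, "voltage_clamp",
                     stimulus = stim_train(c(50, 250)))
  expect_equal(ppr(sw2)$ppr_i, 1, tolerance = 1e-2)
})

test_that("pipeline PPR matches the resource-model closed form", {
  par <- synapse_params(U = 0.55, tau_rec_ms = 200, noise_sd_pA = 0)
  sw <- simulate_ipsc_train(par, stim_train(c(50, 60)))
  expect_equal(ppr(sw)$ppr_i, 1 - 0.55 * exp(-10 / 200),
               tolerance = 0.02)
})

test_that("corrected and uncorrected ratios converge without overlap", {
  par <- synapse_params(U = 0.4, tau_rec_ms = 50, tau_d_ms = 10,
                        noise_sd_pA = 0)
  sw <- simulate_ipsc_train(par, stim_train(c(50, 150)))  # dt = 10 tau_d
  r <- ppr(sw)
  expect_lt(abs(r$ppr_i - r$ppr_raw) / r$ppr_raw, 0.01)
})

test_that("deterministic depression is monotone in the interval", {
  par <- synapse_params(U = 0.6, tau_rec_ms = 50, noise_sd_pA = 0)
  rs <- vapply(c(10, 20, 50, 100, 200, 500, 1000), function(d) {
    ppr(simulate_ipsc_train(par, stim_train(c(50, 50 + d)),
                            total_ms = 50 + d + 150))$ppr_i
  }, numeric(1))
  expect_true(all(diff(rs) > -1e-6))
})

test_that("train responses: identity, overlap bias, generator parity", {
  dt <- 0.1; tau_r <- 0.5; tau_d <- 10
  # five identical, widely spaced IPSCs -> all normalised amplitudes 1
  par_iso <- synapse_params(U = 1, tau_rec_ms = 1e-3, tau_d_ms = tau_d,
                            tau_r_ms = tau_r, noise_sd_pA = 0)
  # tau_rec tiny => full recovery between pulses: equal amplitudes
  sw_iso <- simulate_ipsc_train(par_iso, stim_train(seq(50, 450, 100)))
  tr_iso <- train_response(sw_iso)
  expect_equal(tr_iso$norm_i, rep(1, 5), tolerance = 1e-3)

  # equal underlying amplitudes at 10 ms spacing: residual summation
  # inflates pulses 2-5 by the geometric-series oracle
  times <- seq(50, 90, 10)
  a <- rep(800, 5)
  t <- seq(0, 300 - dt, by = dt)
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  nrm <- exp(-tp / tau_d) - exp(-tp / tau_r)
  i <- rep(-100, length(t))
  for (k in 1:5) {
    dtk <- t - times[k]
    i <- i - ifelse(dtk < 0, 0,
                    a[k] * (exp(-dtk / tau_d) - exp(-dtk / tau_r)) / nrm)
  }
  sw <- sweep_trace(i, dt, "voltage_clamp", stimulus = stim_train(times))
  tr <- train_response(sw)
  expect_true(all(tr$norm_i[2:5] > 1))
  for (k in 2:5) {
    pk <- oracle_kernel_peak(a[1:k], times[1:k], tau_r, tau_d,
                             from = times[k] + 0.3, to = times[k] + 9.5)
    expect_equal(tr$amplitude_pA[k], pk$value, tolerance = 1)
  }

  # depressing train vs kernel-superposed generator ground truth
  par <- synapse_params(U = 0.6, tau_rec_ms = 50, noise_sd_pA = 0)
  stim <- stim_train(seq(50, 90, 10))
  sw2 <- simulate_ipsc_train(par, stim)
  tr2 <- train_response(sw2)
  truth <- attr(sw2, "true_amplitudes_pA")
  pk_truth <- vapply(1:5, function(k)
    oracle_kernel_peak(truth[1:k], stim$pulse_times_ms[1:k], 0.5, 10,
                       from = stim$pulse_times_ms[k] + 0.3,
                       to = stim$pulse_times_ms[k] + 9.5)$value,
    numeric(1))
  expect_equal(tr2$norm_i, pk_truth / pk_truth[1], tolerance = 0.02)
})

test_that("conductance conversion: limits, round trip, defaults", {
  # limiting closed form at R_s = 0, R_m -> infinity
  i <- c(-300, -1200, -50)
  sw <- sweep_trace(rep(i, each = 10), 0.1, "voltage_clamp")
  cp0 <- conductance_params(R_series_MOhm = 0, R_membrane_MOhm = 1e12)
  g <- current_to_conductance(sw, cp0)
  expect_equal(as.numeric(g), rep(i, each = 10) / (-70 - (-2.5)),
               tolerance = 1e-9)

  # forward synthesis from g_true and inversion recover g to 1e-6
  cp <- conductance_params(R_series_MOhm = 19, R_membrane_MOhm = 211)
  t <- seq(0, 100 - 0.1, by = 0.1)
  g_true <- 20 * exp(-(t - 30)^2 / 20) * as.numeric(t > 10)
  i_fwd <- vapply(g_true, function(gg) {
    (gg * (cp$V_hold_mV - cp$E_i_mV) +
       1000 * (cp$V_hold_mV - cp$E_rest_mV) / cp$R_membrane_MOhm) /
      (1 + gg * cp$R_series_MOhm / 1000 +
         cp$R_series_MOhm / cp$R_membrane_MOhm)
  }, numeric(1))
  sw2 <- sweep_trace(i_fwd, 0.1, "voltage_clamp")
  g_back <- current_to_conductance(sw2, cp)
  expect_equal(as.numeric(g_back), g_true, tolerance = 1e-6)

  # the recording-condition constants
  cp_def <- conductance_params(R_series_MOhm = 19, R_membrane_MOhm = 211)
  expect_equal(cp_def$V_hold_mV, -70)
  expect_equal(cp_def$E_rest_mV, -16)
  expect_equal(cp_def$E_i_mV, -2.5)

  # ill-conditioning near E_i is an error naming the time point
  i_bad <- rep(-3560, 100)  # V = -70 + 3.56*19 ~ -2.4 mV ~ E_i
  swb <- sweep_trace(i_bad, 0.1, "voltage_clamp")
  expect_error(current_to_conductance(swb,
                                      conductance_params(19, 211)),
               "ill-conditioned")
})

test_that("conductance PPR equals current PPR in the linear limit", {
  par <- synapse_params(U = 0.55, tau_rec_ms = 100, noise_sd_pA = 0)
  sw <- simulate_ipsc_train(par, stim_train(c(50, 70)))
  cp <- conductance_params(R_series_MOhm = 0, R_membrane_MOhm = 1e12)
  r <- ppr(sw, params = cp)
  expect_equal(r$ppr_g, r$ppr_i, tolerance = 1e-6)
})

test_that("unitary amplitude averages the single-pulse repeats", {
  mk <- function(amp) {
    t <- seq(0, 200 - 0.1, by = 0.1)
    kern <- ipsc_peak_kernel(t - 50, 0.5, 10)
    sweep_trace(-100 - amp * kern, 0.1, "voltage_clamp",
                stimulus = stim_train(50))
  }
  ipsc_peak_kernel <- function(tt, tau_r, tau_d) {
    tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
    nrm <- exp(-tp / tau_d) - exp(-tp / tau_r)
    ifelse(tt < 0, 0, (exp(-tt / tau_d) - exp(-tt / tau_r)) / nrm)
  }
  u1 <- unitary_amplitude(list(mk(1200), mk(1200), mk(1200)))
  expect_equal(u1$amplitude_nA, 1.2, tolerance = 1e-3)
  u2 <- unitary_amplitude(list(mk(1000), mk(1100), mk(1200)))
  expect_equal(u2$amplitude_nA, 1.1, tolerance = 1e-3)
  expect_error(unitary_amplitude(list()), "no usable")
})
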