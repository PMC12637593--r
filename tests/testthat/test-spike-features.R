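test_that("detection: silence, templates at known times, oracle parity", {
  flat <- sweep_trace(rep(-70, 5000), 0.02, "current_clamp")
  expect_identical(detect_aps(flat), integer(0))

  times <- seq(5, 93, by = 8)[1:12]
  sw <- make_spike_trace(times, total_ms = 100)
  pk <- detect_aps(sw)
  expect_length(pk, 12L)
  expect_equal((pk - 1) * sw$dt_ms, times, tolerance = sw$dt_ms)

  par <- fs_neuron_params(noise_sd_pA = 0)
  sim <- simulate_fs_neuron(par, step_protocol(600), dt_ms = 0.02)
  expect_identical(detect_aps(sim),
                   oracle_detect(sim$samples, sim$dt_ms))
})

test_that("threshold: constant-slope and exponential-upstroke closed forms", {
  dt <- 0.02
  # piecewise-linear upstroke of constant slope from -70: every upstroke
  # sample exceeds 4% of max, so threshold is the first upstroke sample
  t <- seq(0, 20 - dt, by = dt)
  v <- rep(-70, length(t))
  ramp <- t >= 10 & t <= 12
  v[ramp] <- -70 + 50 * (t[ramp] - 10) / 2
  sw <- sweep_trace(v, dt, "current_clamp")
  pk <- which.max(v)
  th <- ap_threshold(sw, pk, window_ms = 5)
  # central differences smear the corner by one sample
  expect_lt(abs(th$threshold_V_mV - (-70)), 50 / 2 * dt * 2 + 0.1)

  # exponential upstroke: dV/dt = (V - V0)/tau, max at peak, so the 4%
  # crossing is where V - V0 = 0.04 (Vp - V0)
  tau <- 0.5
  v0 <- -70; vp <- 30; tp <- 15
  v2 <- ifelse(t <= tp, v0 + (vp - v0) * exp((t - tp) / tau), v0)
  sw2 <- sweep_trace(v2, dt, "current_clamp")
  pk2 <- which.max(v2)
  th2 <- ap_threshold(sw2, pk2, window_ms = 6)
  analytic <- v0 + 0.04 * (vp - v0)
  expect_lt(abs(th2$threshold_V_mV - analytic),
            (vp - v0) * 0.04 * (exp(dt / tau) - 1) + 0.2)
  # the sampled maximum of dV/dt sits one sample inside the kink, so
  # allow the e^(-dt/tau) discretisation factor
  expect_equal(th2$max_slope_V_per_s, (vp - v0) / tau,
               tolerance = 0.05)
})

test_that("height is threshold-referenced and translation invariant", {
  expect_equal(ap_height(-42, -42), 0)
  expect_equal(ap_height(43, -42), 85)
  expect_error(ap_height(-50, -42), "malformed")

  sw <- make_spike_trace(10, total_ms = 20)
  ev1 <- ap_events(sw)
  sw2 <- sw; sw2$samples <- sw$samples + 7.3
  ev2 <- ap_events(sw2)
  expect_equal(ev2$height_mV, ev1$height_mV, tolerance = 1e-9)
  expect_equal(ev2$half_width_ms, ev1$half_width_ms, tolerance = 1e-9)
  expect_equal(ev2$threshold_V_mV, ev1$threshold_V_mV + 7.3,
               tolerance = 1e-9)
  expect_equal(ev2$max_slope_V_per_s, ev1$max_slope_V_per_s,
               tolerance = 1e-9)
})

test_that("half-width: triangle and gaussian closed forms", {
  dt <- 0.02
  # isoceles triangle with base 1 ms measured at its own baseline:
  # measured from half height, width is half the base
  sw <- make_spike_trace(10, total_ms = 20, shape = "triangle",
                         height = 100, width_ms = 1)
  pk <- which.max(sw$samples)
  thr <- -70  # baseline = threshold for a triangle rising from flat
  expect_equal(ap_half_width(sw, pk, thr), 0.5, tolerance = 2 * dt)

  # gaussian spike of SD sigma above threshold: FWHM = 2 sigma sqrt(2 ln 2)
  sigma <- 0.4
  sw2 <- make_spike_trace(10, total_ms = 20, shape = "gaussian",
                          height = 90, width_ms = sigma)
  pk2 <- which.max(sw2$samples)
  expect_equal(ap_half_width(sw2, pk2, -70),
               2 * sigma * sqrt(2 * log(2)), tolerance = dt)
})

test_that("interspike potential: flat segment and half-sine trough", {
  dt <- 0.02
  t <- seq(0, 40 - dt, by = dt)
  v <- rep(-70, length(t))
  v[t >= 10 & t < 10.2] <- 20
  v[t >= 30 & t < 30.2] <- 20
  sw <- sweep_trace(v, dt, "current_clamp")
  pks <- detect_aps(sw)
  expect_equal(interspike_potential(sw, pks[1], pks[2]), -70)

  trough <- t > 15 & t < 25
  v2 <- v
  v2[trough] <- -70 - 8 * sin(pi * (t[trough] - 15) / 10)
  sw2 <- sweep_trace(v2, dt, "current_clamp")
  expect_equal(interspike_potential(sw2, pks[1], pks[2]), -78,
               tolerance = 8 * (pi * dt / 10)^2 + 1e-6)
})

test_that("randomized spikes agree with brute-force oracles", {
  # >= 100 random synthetic spikes; times within 1 sample, voltages
  # within 0.1 mV, widths/slopes within 2%
  set.seed(101)
  for (i in 1:100) {
    sw <- random_spike_trace()
    dt <- sw$dt_ms
    pk <- detect_aps(sw)
    opk <- oracle_detect(sw$samples, dt)
    expect_identical(pk, opk)
    ev <- ap_events(sw)
    i0 <- max(1L, pk[1] - as.integer(round(2 / dt)))
    oth <- oracle_threshold(sw$samples, dt, i0, pk[1])
    expect_lt(abs(ev$threshold_V_mV[1] - oth$threshold), 0.1)
    expect_lt(abs(ev$max_slope_V_per_s[1] - oth$max_slope) /
                oth$max_slope, 0.02)
    v_half <- ev$threshold_V_mV[1] +
      (ev$peak_V_mV[1] - ev$threshold_V_mV[1]) / 2
    ohw <- oracle_half_width(sw$samples, dt, pk[1], v_half)
    expect_lt(abs(ev$half_width_ms[1] - ohw) / ohw, 0.02)
  }
})

test_that("resampling to half the interval changes widths < 2%", {
  # logistic-rise / exponential-decay spikes whose dV/dt transient is
  # well resolved at both sampling rates; the coarse trace is the fine
  # trace downsampled so both measurements see the same data
  set.seed(11)
  for (i in 1:10) {
    w <- runif(1, 0.1, 0.3)
    tau_d <- runif(1, 0.3, 0.8)
    t <- seq(0, 30 - 0.01, by = 0.01)
    tp <- 15
    v <- -75 + 170 / (1 + exp(-(t - tp) / w)) *
      ifelse(t <= tp, 1, exp(-(t - tp) / tau_d))
    fine <- sweep_trace(v, 0.01, "current_clamp")
    coarse <- sweep_trace(v[seq(1, length(v), by = 2)], 0.02,
                          "current_clamp")
    a <- ap_events(coarse)
    b <- ap_events(fine)
    expect_lt(abs(a$half_width_ms[1] - b$half_width_ms[1]) /
                b$half_width_ms[1], 0.02)
    expect_lt(abs(a$max_slope_V_per_s[1] - b$max_slope_V_per_s[1]) /
                b$max_slope_V_per_s[1], 0.02)
  }
})

test_that("trace selection follows the first->=10-AP rule", {
  # synthetic cell whose sweeps carry 3, 8, 12, 20 spikes
  counts <- c(3, 8, 12, 20)
  sweeps <- lapply(seq_along(counts), function(k) {
    times <- seq(60, by = 10, length.out = counts[k])
    sw <- make_spike_trace(times, total_ms = 300, dt = 0.05)
    sw$stimulus <- step_protocol(100 * k, 50, 200)
    sw$sweep_id <- paste0("s", k)
    sw
  })
  cell <- cell_recording("sel1", "WT/WT", sweeps)
  ts <- select_trace(cell)
  expect_identical(ts$sweep_id, "s3")
  expect_equal(ts$n_APs, 12)
  expect_equal(ts$firing_rate_Hz, 12 / 0.2)

  # all counts < 10 -> selection error
  cell2 <- cell_recording("sel2", "WT/WT", sweeps[1:2])
  expect_error(select_trace(cell2), ">= 10 APs")

  # boundary: counts 10 and 30 -> the 10-AP sweep, AP_10 is its last AP
  sweeps3 <- lapply(c(10, 30), function(n) {
    times <- seq(60, by = 6, length.out = n)
    sw <- make_spike_trace(times, total_ms = 300, dt = 0.05)
    sw$stimulus <- step_protocol(ifelse(n == 10, 100, 200), 50, 200)
    sw$sweep_id <- paste0("n", n)
    sw
  })
  ts3 <- select_trace(cell_recording("sel3", "WT/WT", sweeps3))
  expect_identical(ts3$sweep_id, "n10")
  expect_equal(unname(ts3$at_ap10["half_width_ms"]),
               ts3$events$half_width_ms[10])
})
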