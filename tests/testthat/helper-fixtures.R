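# Synthetic trace builders and brute-force oracles shared across tests.
# Oracles are deliberately naive, independent re-implementations of the
# rules under test.

# flat trace with spike templates added at given peak times
make_spike_trace <- function(peak_times_ms, total_ms = 100, dt = 0.02,
                             baseline = -70,
                             shape = c("triangle", "gaussian"),
                             height = 100, width_ms = 1) {
  shape <- match.arg(shape)
  t <- seq(0, total_ms - dt, by = dt)
  v <- rep(baseline, length(t))
  for (tp in peak_times_ms) {
    if (shape == "triangle") {
      rise <- t >= tp - width_ms / 2 & t <= tp
      fall <- t > tp & t <= tp + width_ms / 2
      v[rise] <- pmax(v[rise],
                      baseline + height * (1 - (tp - t[rise]) / (width_ms / 2)))
      v[fall] <- pmax(v[fall],
                      baseline + height * (1 - (t[fall] - tp) / (width_ms / 2)))
    } else {
      sd_ms <- width_ms
      v <- pmax(v, baseline + height * exp(-(t - tp)^2 / (2 * sd_ms^2)))
    }
  }
  sweep_trace(v, dt_ms = dt, modality = "current_clamp")
}

# brute-force AP detector: samples greater than both neighbours and above
# the cutoff, with the refractory gap enforced in time order
oracle_detect <- function(v, dt, cutoff = 0, gap_ms = 1) {
  keep <- integer(0)
  last <- -Inf
  for (i in 2:(length(v) - 1)) {
    if (v[i] > cutoff && v[i] > v[i - 1] && v[i] >= v[i + 1] &&
        (i - last) >= gap_ms / dt) {
      keep <- c(keep, i)
      last <- i
    }
  }
  keep
}

# brute-force threshold/slope oracle on an upstroke window
oracle_threshold <- function(v, dt, i0, peak, frac = 0.04) {
  dvdt <- rep(NA_real_, length(v))
  for (i in 2:(length(v) - 1)) dvdt[i] <- (v[i + 1] - v[i - 1]) / (2 * dt)
  ms <- -Inf
  for (i in i0:peak) if (is.finite(dvdt[i]) && dvdt[i] > ms) ms <- dvdt[i]
  for (i in i0:peak) {
    if (is.finite(dvdt[i]) && dvdt[i] > frac * ms)
      return(list(threshold = v[i], index = i, max_slope = ms))
  }
  NULL
}

# brute-force half-width by dense linear interpolation around the peak
oracle_half_width <- function(v, dt, peak, v_half) {
  ri <- peak
  while (ri > 1 && v[ri - 1] > v_half) ri <- ri - 1
  fi <- peak
  while (fi < length(v) && v[fi + 1] > v_half) fi <- fi + 1
  tr <- (ri - 2) * dt + dt * (v_half - v[ri - 1]) / (v[ri] - v[ri - 1])
  tf <- (fi - 1) * dt + dt * (v[fi] - v_half) / (v[fi] - v[fi + 1])
  tf - tr
}

# random plausible single-spike trace for the randomized oracle suite:
# exponential-ish upstroke, gaussian cap, exponential repolarisation
random_spike_trace <- function(dt = 0.02) {
  base <- runif(1, -80, -65)
  peak_v <- runif(1, 10, 50)
  up_tau <- runif(1, 0.15, 0.6)
  down_tau <- runif(1, 0.2, 0.8)
  t <- seq(0, 30 - dt, by = dt)
  tp <- runif(1, 10, 15)
  v <- ifelse(t <= tp,
              base + (peak_v - base) * exp((t - tp) / up_tau),
              base + (peak_v - base) * exp(-(t - tp) / down_tau))
  sweep_trace(v, dt_ms = dt, modality = "current_clamp")
}

# dense-grid oracle for the peak of a superposition of IPSC kernels
oracle_kernel_peak <- function(amps, times, tau_r, tau_d, from, to,
                               res = 1e-4) {
  tt <- seq(from, to, by = res)
  y <- rep(0, length(tt))
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  norm <- exp(-tp / tau_d) - exp(-tp / tau_r)
  for (k in seq_along(amps)) {
    dtk <- tt - times[k]
    y <- y + ifelse(dtk < 0, 0,
                    amps[k] * (exp(-dtk / tau_d) - exp(-dtk / tau_r)) / norm)
  }
  list(t = tt[which.max(y)], value = max(y))
}
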