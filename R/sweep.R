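#' Stimulus descriptions
#'
#' A `step_protocol` describes a rectangular current step delivered in
#' current clamp; a `stim_train` describes a train of brief presynaptic
#' current pulses used to evoke action potentials in the presynaptic cell
#' of a paired recording.
#'
#' @param amplitude_pA Signed step amplitude in pA.
#' @param onset_ms Step onset, ms from sweep start (>= 0).
#' @param duration_ms Step duration in ms (> 0).
#' @return An object of class `"step_protocol"`.
#' @examples
#' step_protocol(600, onset_ms = 100, duration_ms = 500)
#' @export
step_protocol <- function(amplitude_pA, onset_ms = 100, duration_ms = 500) {
  stopifnot(is.numeric(amplitude_pA), length(amplitude_pA) == 1L,
            is.finite(amplitude_pA))
  if (duration_ms <= 0) stop("step duration_ms must be > 0")
  if (onset_ms < 0) stop("step onset_ms must be >= 0")
  structure(list(type = "step", amplitude_pA = amplitude_pA,
                 onset_ms = onset_ms, duration_ms = duration_ms),
            class = "step_protocol")
}

#' @rdname step_protocol
#' @param pulse_times_ms Strictly increasing pulse onset times, ms.
#' @param pulse_amplitude_nA Pulse amplitude in nA; the experimental
#'   protocol this emulates used the minimal current between 1 and 2 nA.
#' @param pulse_width_ms Pulse width in ms (default 1).
#' @return An object of class `"stim_train"`.
#' @export
stim_train <- function(pulse_times_ms, pulse_amplitude_nA = 1.5,
                       pulse_width_ms = 1) {
  pulse_times_ms <- as.numeric(pulse_times_ms)
  if (length(pulse_times_ms) < 1L || any(!is.finite(pulse_times_ms)))
    stop("pulse_times_ms must be a non-empty finite vector")
  if (is.unsorted(pulse_times_ms, strictly = TRUE))
    stop("pulse_times_ms must be strictly increasing")
  if (pulse_amplitude_nA < 1 || pulse_amplitude_nA > 2)
    warning("pulse_amplitude_nA outside the 1-2 nA protocol range")
  structure(list(type = "train", pulse_times_ms = pulse_times_ms,
                 pulse_amplitude_nA = pulse_amplitude_nA,
                 pulse_width_ms = pulse_width_ms),
            class = "stim_train")
}

#' A single digitized sweep
#'
#' A sweep is one digitized trace: membrane voltage (mV) for current-clamp
#' recordings or membrane current (pA) for voltage-clamp recordings,
#' sampled at a fixed interval, together with its stimulus description.
#' Voltage-clamp current uses amplifier convention (inward current
#' negative); downstream amplitudes are reported as positive magnitudes.
#'
#' @param samples Numeric vector of measurements (mV or pA).
#' @param dt_ms Sampling interval in ms (> 0); 0.02 ms is 50 kHz.
#' @param modality `"current_clamp"` or `"voltage_clamp"`.
#' @param stimulus A [step_protocol()] or [stim_train()] (or `NULL`).
#' @param sweep_id Identifier string.
#' @return An object of class `"fs_sweep"`.
#' @examples
#' sw <- sweep_trace(rep(-70, 1000), dt_ms = 0.02, modality = "current_clamp")
#' sweep_duration(sw)
#' @export
sweep_trace <- function(samples, dt_ms, modality = c("current_clamp",
                        "voltage_clamp"), stimulus = NULL,
                        sweep_id = "sweep_1") {
  modality <- match.arg(modality)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("sweep has no samples")
  if (!all(is.finite(samples))) stop("sweep contains non-finite samples")
  if (!is.numeric(dt_ms) || length(dt_ms) != 1L || !is.finite(dt_ms) ||
      dt_ms <= 0)
    stop("dt_ms must be a single positive number")
  dur <- length(samples) * dt_ms
  if (!is.null(stimulus)) {
    ev <- stimulus_events(stimulus)
    if (any(ev < 0) || any(ev >= dur))
      stop("stimulus events must lie within [0, ", format(dur), ") ms")
  }
  structure(list(samples = samples, dt_ms = dt_ms, modality = modality,
                 stimulus = stimulus, sweep_id = as.character(sweep_id)),
            class = "fs_sweep")
}

# event times (ms) a stimulus claims within the sweep
stimulus_events <- function(stimulus) {
  if (is.null(stimulus)) return(numeric(0))
  switch(stimulus$type,
         step  = c(stimulus$onset_ms,
                   stimulus$onset_ms + stimulus$duration_ms - 1e-9),
         train = stimulus$pulse_times_ms,
         stop("unknown stimulus type: ", stimulus$type))
}

#' @export
print.fs_sweep <- function(x, ...) {
  cat(sprintf("<fs_sweep %s> %s, %d samples @ %g ms (%.1f ms), %s\n",
              x$sweep_id, x$modality, length(x$samples), x$dt_ms,
              sweep_duration(x),
              if (is.null(x$stimulus)) "no stimulus" else x$stimulus$type))
  invisible(x)
}

#' @rdname sweep_trace
#' @param sweep An `fs_sweep`.
#' @return `sweep_duration()`: sweep length in ms; `sweep_times()`: vector
#'   of sample times in ms (0 at sweep start).
#' @export
sweep_duration <- function(sweep) length(sweep$samples) * sweep$dt_ms

#' @rdname sweep_trace
#' @export
sweep_times <- function(sweep) (seq_along(sweep$samples) - 1) * sweep$dt_ms

#' Units implied by a sweep's modality
#' @param sweep An `fs_sweep`.
#' @return `"mV"` or `"pA"`.
#' @export
sweep_units <- function(sweep) {
  switch(sweep$modality, current_clamp = "mV", voltage_clamp = "pA")
}

# loud unit-safety guard used by every consumer of a sweep
assert_modality <- function(sweep, modality) {
  if (!inherits(sweep, "fs_sweep"))
    stop("expected an fs_sweep object")
  if (!identical(sweep$modality, modality))
    stop(sprintf("operation requires a %s sweep but '%s' is %s",
                 modality, sweep$sweep_id, sweep$modality))
  invisible(sweep)
}

#' Passive membrane properties
#'
#' Container for passive properties measured per cell, with the
#' quality-control bounds used for whole-cell recordings: series
#' resistance at most 20 MOhm in current clamp or 30 MOhm in voltage
#' clamp, and holding current magnitude at most 200 pA.
#'
#' @param R_series_MOhm Series (access) resistance, MOhm.
#' @param R_membrane_MOhm Membrane (input) resistance, MOhm.
#' @param tau_ms Membrane time constant, ms.
#' @param C_m_pF Membrane capacitance, pF.
#' @param V_rest_mV Resting membrane potential, mV.
#' @param holding_current_pA Holding current, pA.
#' @return An object of class `"passive_props"`.
#' @export
passive_props <- function(R_series_MOhm = NA_real_,
                          R_membrane_MOhm = NA_real_, tau_ms = NA_real_,
                          C_m_pF = NA_real_, V_rest_mV = NA_real_,
                          holding_current_pA = NA_real_) {
  for (r in c(R_series_MOhm, R_membrane_MOhm))
    if (!is.na(r) && r <= 0) stop("resistances must be positive")
  structure(list(R_series_MOhm = R_series_MOhm,
                 R_membrane_MOhm = R_membrane_MOhm, tau_ms = tau_ms,
                 C_m_pF = C_m_pF, V_rest_mV = V_rest_mV,
                 holding_current_pA = holding_current_pA),
            class = "passive_props")
}

#' A per-cell collection of sweeps
#'
#' Groups the sweeps acquired from one cell (or one synaptically connected
#' pair, recorded on the postsynaptic side) with its genotype label and
#' recording metadata. Genotype labels follow the three-level allele
#' nomenclature `WT/WT`, `Cre/WT`, `Cre/Cre` (two, one, or no functional
#' copies of the silent-subunit gene).
#'
#' @param cell_id Identifier string.
#' @param genotype One of `"WT/WT"`, `"Cre/WT"`, `"Cre/Cre"`.
#' @param sweeps List of [sweep_trace()] objects, in acquisition order.
#' @param region Free-text region/layer label.
#' @param holding_condition `"endogenous_rest"` or `"held_minus70"`.
#' @param passive Optional [passive_props()].
#' @return An object of class `"cell_recording"`.
#' @export
cell_recording <- function(cell_id, genotype = c("WT/WT", "Cre/WT",
                           "Cre/Cre"), sweeps, region = "S1 L2/3",
                           holding_condition = c("held_minus70",
                           "endogenous_rest"), passive = NULL) {
  genotype <- match.arg(genotype)
  holding_condition <- match.arg(holding_condition)
  if (!is.list(sweeps) || length(sweeps) == 0L)
    stop("sweeps must be a non-empty list")
  ok <- vapply(sweeps, inherits, logical(1), what = "fs_sweep")
  if (!all(ok)) stop("all sweeps must be fs_sweep objects")
  ids <- vapply(sweeps, `[[`, character(1), "sweep_id")
  if (anyDuplicated(ids)) stop("duplicate sweep_id in cell")
  names(sweeps) <- ids
  structure(list(cell_id = as.character(cell_id), genotype = genotype,
                 region = region, holding_condition = holding_condition,
                 sweeps = sweeps, passive = passive),
            class = "cell_recording")
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf("<cell_recording %s> genotype %s, %d sweeps, %s\n",
              x$cell_id, x$genotype, length(x$sweeps), x$region))
  invisible(x)
}

#' Quality-control report for a cell
#'
#' Applies the recording QC rules: series resistance at most 20 MOhm for
#' current-clamp cells and 30 MOhm for voltage-clamp cells, and holding
#' current magnitude at most 200 pA. Rules whose inputs are missing are
#' reported as `"not evaluated"`. The cell is never modified.
#'
#' @param cell A [cell_recording()].
#' @return A data.frame with columns `rule`, `value`, `bound`, `status`
#'   (`"pass"`, `"fail"`, or `"not evaluated"`).
#' @examples
#' sw <- sweep_trace(rep(-74, 100), 0.02, "current_clamp")
#' cl <- cell_recording("c1", "WT/WT", list(sw),
#'                      passive = passive_props(R_series_MOhm = 11.1))
#' qc_cell(cl)
#' @export
qc_cell <- function(cell) {
  stopifnot(inherits(cell, "cell_recording"))
  mods <- unique(vapply(cell$sweeps, `[[`, character(1), "modality"))
  rs_bound <- if ("voltage_clamp" %in% mods) 30 else 20
  p <- cell$passive
  row <- function(rule, value, bound) {
    status <- if (is.null(p) || is.na(value)) "not evaluated"
              else if (value <= bound) "pass" else "fail"
    data.frame(rule = rule, value = value, bound = bound, status = status,
               stringsAsFactors = FALSE)
  }
  rs <- if (is.null(p)) NA_real_ else p$R_series_MOhm
  hc <- if (is.null(p)) NA_real_ else abs(p$holding_current_pA)
  rbind(row(sprintf("R_series <= %d MOhm (%s)", rs_bound,
                    if (rs_bound == 30) "voltage clamp" else "current clamp"),
            rs, rs_bound),
        row("|holding current| <= 200 pA", hc, 200))
}
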